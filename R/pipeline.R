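#' Pipeline configuration
#'
#' Bundles one input source (a `count_matrix`, a count table + sample sheet on
#' disk, a directory of RCC lane files + sample sheet, or a
#' [simulation_config()]) with every tunable constant of the workflow.
#'
#' @param matrix a `count_matrix` (in-memory input source).
#' @param count_table,sample_sheet paths (file input source).
#' @param rcc_dir directory of `.RCC` lane files (+ `sample_sheet`).
#' @param simulation a `simulation_config` (synthetic input source).
#' @param fraction which fraction to analyse (`cell_fraction` uses the
#'   top-`top_n` endogenous reference; `ev_fraction` the spike-ins).
#' @param min_rin RIN gate, exclusive (default 7).
#' @param max_below_frac low-coverage sample removal boundary (default 0.40).
#' @param min_detect_frac robust-probe detection boundary (default 0.75).
#' @param top_n reference-set size for the cellular fraction (default 100).
#' @param p_sig,p_trend significance tiers (defaults 0.05, 0.1).
#' @param chauvenet_sd,chauvenet_min_keep outlier-adjustment band (SD units)
#'   and per-group retention floor (defaults 2, 10).
#' @param out_dir optional output directory; when set, all result tables and
#'   reports are written there as TSV/JSON.
#' @param seed integer seed (drives simulation; the analysis itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix = NULL, count_table = NULL,
                            sample_sheet = NULL, rcc_dir = NULL,
                            simulation = NULL,
                            fraction = c("cell_fraction", "ev_fraction"),
                            min_rin = 7.0, max_below_frac = 0.40,
                            min_detect_frac = 0.75, top_n = 100,
                            p_sig = 0.05, p_trend = 0.1,
                            chauvenet_sd = 2, chauvenet_min_keep = 10,
                            out_dir = NULL, seed = 1L) {
  fraction <- normalize_fraction(match.arg(fraction))
  sources <- c(!is.null(matrix), !is.null(count_table), !is.null(rcc_dir),
               !is.null(simulation))
  if (sum(sources) != 1)
    stop("exactly one input source must be given (matrix, count_table, rcc_dir or simulation)",
         call. = FALSE)
  stopifnot(max_below_frac > 0, max_below_frac <= 1,
            min_detect_frac > 0, min_detect_frac <= 1,
            p_sig > 0, p_sig < p_trend, p_trend <= 1, chauvenet_sd > 0)
  structure(list(matrix = matrix, count_table = count_table,
                 sample_sheet = sample_sheet, rcc_dir = rcc_dir,
                 simulation = simulation, fraction = fraction,
                 min_rin = min_rin, max_below_frac = max_below_frac,
                 min_detect_frac = min_detect_frac, top_n = top_n,
                 p_sig = p_sig, p_trend = p_trend,
                 chauvenet_sd = chauvenet_sd,
                 chauvenet_min_keep = chauvenet_min_keep,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments; a
#' `simulation:` block is handed to [simulation_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation))
    y$simulation <- do.call(simulation_config, y$simulation)
  do.call(pipeline_config, y)
}

pipeline_input <- function(config) {
  if (!is.null(config$matrix)) {
    list(matrix = config$matrix, truth = NULL)
  } else if (!is.null(config$count_table)) {
    list(matrix = read_count_table(config$count_table, config$sample_sheet),
         truth = NULL)
  } else if (!is.null(config$rcc_dir)) {
    files <- sort(list.files(config$rcc_dir, pattern = "\\.[Rr][Cc][Cc]$",
                             full.names = TRUE))
    records <- lapply(files, read_rcc)
    list(matrix = rcc_to_count_matrix(records,
                                      read_sample_sheet(config$sample_sheet)),
         truth = NULL)
  } else {
    sim <- simulate_counts(config$simulation)
    list(matrix = sim$matrix, truth = sim$truth)
  }
}

#' Run the full single-fraction discovery pipeline
#'
#' Stage order: ingest (or simulate) -> RIN gate -> background threshold from
#' negative controls -> reference-geomean normalization factors (top-n
#' endogenous probes for the cellular fraction, spike-ins for the EV
#' fraction) -> detection censoring -> low-coverage sample removal -> robust
#' probe selection -> normality-branched differential testing with Chauvenet
#' re-testing of candidates -> ROC per significant probe -> heatmap leaf
#' order of significant probes. Deterministic given the config and seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`: `threshold`, `factors`, `filter_log`,
#'   `de_table`, `roc` (data.frame), `leaf_order` (or `NULL` when fewer than
#'   two significant probes), `robust_probes`, `analyzed_samples`,
#'   `n_endogenous`, `truth` (simulation ground truth or `NULL`), `config`,
#'   `version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  input <- pipeline_input(config)
  mat <- input$matrix

  frac_samples <- mat$samples$sample_id[mat$samples$fraction == config$fraction]
  if (length(frac_samples) == 0)
    stop("pipeline stage 'ingest': no samples of fraction ", config$fraction,
         call. = FALSE)
  mat <- subset_count_matrix(mat, samples = frac_samples)
  filter_log <- list()

  rin <- filter_by_rin(mat$samples, min_rin = config$min_rin)
  filter_log <- c(filter_log, list(rin$log))
  mat <- subset_count_matrix(mat, samples = rin$kept)

  threshold <- background_threshold(mat)
  reference <- if (config$fraction == "cell_fraction") "top_n" else "spikein"
  factors <- reference_factors(mat, reference = reference, n = config$top_n)
  norm <- apply_normalization(mat, factors, threshold)

  mask <- detection_mask(norm)
  cov <- drop_low_coverage_samples(mask, max_below_frac = config$max_below_frac)
  filter_log <- c(filter_log, list(cov$log))
  mask$detected <- mask$detected[, cov$kept, drop = FALSE]

  groups <- sample_groups(mat)[cov$kept]
  robust <- robust_probe_filter(mask, groups,
                                min_frac = config$min_detect_frac)
  filter_log <- c(filter_log, list(robust$log))

  de <- run_de(norm, robust$kept, groups, p_sig = config$p_sig,
               p_trend = config$p_trend, chauvenet_sd = config$chauvenet_sd,
               chauvenet_min_keep = config$chauvenet_min_keep)
  filter_log <- c(filter_log, list(attr(de, "excluded")))

  sig <- de$probe_id[de$tier == "significant"]
  vals <- attr(de, "values")
  roc <- lapply(sig, function(p) {
    v <- vals[[p]]
    r <- roc_auc_ci(c(v$case, v$control),
                    rep(c("case", "control"),
                        c(length(v$case), length(v$control))),
                    variable_id = p)
    data.frame(probe_id = p, auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high, orientation = r$orientation,
               n_case = r$n_case, n_control = r$n_control,
               stringsAsFactors = FALSE)
  })
  roc <- if (length(roc)) do.call(rbind, roc) else
    data.frame(probe_id = character(0), auc = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), orientation = character(0),
               n_case = integer(0), n_control = integer(0),
               stringsAsFactors = FALSE)

  leaf <- if (length(sig) >= 2)
    cluster_leaf_order(norm$values[sig, cov$kept, drop = FALSE]) else NULL

  report <- structure(
    list(threshold = threshold, factors = factors, filter_log = filter_log,
         de_table = de, roc = roc, leaf_order = leaf,
         robust_probes = robust$kept, analyzed_samples = cov$kept,
         n_endogenous = sum(mat$probes$code_class == "Endogenous"),
         truth = input$truth, config = config,
         version = as.character(utils::packageVersion("nanomir"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("nanomir run (", x$config$fraction, ")\n", sep = "")
  print(x$threshold)
  cat("  samples analyzed: ", length(x$analyzed_samples),
      "; robust probes: ", length(x$robust_probes), "\n", sep = "")
  cat("  significant: ", sum(x$de_table$tier == "significant"),
      "; trends: ", sum(x$de_table$tier == "trend"), "\n", sep = "")
  invisible(x)
}

#' Cross-fraction Venn bookkeeping of two run reports
#'
#' @param report_a,report_b `run_report`s of the two fractions (sharing one
#'   panel).
#' @return a [venn_partition()] of the robust probe sets over the endogenous
#'   panel universe.
#' @export
compare_fractions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "run_report"), inherits(report_b, "run_report"))
  if (report_a$n_endogenous != report_b$n_endogenous)
    stop("fraction runs use different panel universes", call. = FALSE)
  venn_partition(report_a$robust_probes, report_b$robust_probes,
                 report_a$n_endogenous)
}

#' Write all artifacts of a run report to a directory
#'
#' Emits `de_table.tsv`, `roc.tsv`, `factors.tsv`, `robust_probes.tsv`,
#' `threshold.json`, `filter_log.json`, `leaf_order.json` and a `report.json`
#' summary. Output is deterministic: the same report always produces
#' byte-identical files.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    eol = "\n")
  de <- as.data.frame(report$de_table)
  de$statistic <- sprintf("%.10g", de$statistic)
  de$p <- sprintf("%.10g", de$p)
  de$p_bh <- sprintf("%.10g", de$p_bh)
  de$pct_change <- sprintf("%.10g", de$pct_change)
  wt(de, "de_table.tsv")
  roc <- report$roc
  for (col in c("auc", "ci_low", "ci_high"))
    roc[[col]] <- sprintf("%.10g", roc[[col]])
  wt(roc, "roc.tsv")
  wt(data.frame(sample_id = names(report$factors),
                factor = sprintf("%.10g", unname(report$factors))),
     "factors.tsv")
  wt(data.frame(probe_id = report$robust_probes), "robust_probes.tsv")
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wj(unclass(report$threshold), "threshold.json")
  wj(report$filter_log, "filter_log.json")
  if (!is.null(report$leaf_order))
    wj(list(order = report$leaf_order$order,
            height = report$leaf_order$height,
            inversions = report$leaf_order$inversions),
       "leaf_order.json")
  wj(list(fraction = report$config$fraction,
          threshold = report$threshold$threshold,
          n_samples_analyzed = length(report$analyzed_samples),
          n_robust_probes = length(report$robust_probes),
          n_significant = sum(report$de_table$tier == "significant"),
          n_trend = sum(report$de_table$tier == "trend"),
          seed = report$config$seed, version = report$version),
     "report.json")
  invisible(dir)
}
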