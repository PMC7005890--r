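## Synthetic two-group NanoString-style panels with known ground truth.
## Counts follow a negative-binomial (Poisson-gamma) model: per-probe means
## are drawn once from a log-normal baseline, per-sample technical scale
## factors perturb all probes of a lane, and the case group's means are
## multiplied/divided by the planted fold for differentially expressed probes.

## One RNG stream per operation: the stream seed combines the config seed with
## a hash of the operation name, so adding operations never shifts existing
## draws. Kept below 2^31 (R integers are 32-bit).
op_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  (as.integer(seed) %% 1000000L) * 2039L + (h %% 2039L)
}

#' Simulation configuration for a synthetic nCounter-style miRNA panel
#'
#' Defaults emulate the profiled study conditions: a ~800-probe human miRNA
#' codeset (798 endogenous probes), 8 negative ligation controls, 6 non-human
#' spike-in probes, and two groups of 15 samples. The two fraction profiles
#' differ in baseline abundance and overdispersion so that background
#' thresholds and detection rates differ: the cellular profile lands its
#' threshold in the high tens of counts and the EV profile in the low tens.
#'
#' @param n_endogenous,n_negative,n_spikein panel composition.
#' @param n_case,n_control group sizes.
#' @param fraction_profile `"cell_fraction"` (PBMC-like: high baseline, lower
#'   dispersion) or `"ev_fraction"` (low baseline, higher dispersion).
#' @param baseline_log_mean,baseline_log_sd log-scale (natural log) mean/sd of
#'   per-probe expected counts; profile defaults 7.0/1.2 (cell) and 4.8/1.6 (EV).
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi mu^2); profile defaults 0.12 (cell) and 0.30 (EV).
#' @param neg_mean mean of the negative-ligation-control count model
#'   (group-independent); profile defaults 40 (cell) and 10 (EV).
#' @param spike_mean,spike_dispersion spike-in count model: high mean, low
#'   variance, shared across samples apart from technical scale.
#' @param sample_scale_sd log-sd of the per-sample technical scale factor
#'   applied to every probe of a lane.
#' @param n_de number of planted differentially expressed endogenous probes.
#' @param fold_range fold-effect range (both > 1) the planted effects are drawn
#'   from; up-probes have case means multiplied, down-probes divided.
#' @param outlier_rate,outlier_multiplier defaults handed to
#'   [inject_outliers()] by the pipeline.
#' @param seed integer master seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_endogenous = 798L, n_negative = 8L,
                              n_spikein = 6L, n_case = 15L, n_control = 15L,
                              fraction_profile = c("cell_fraction", "ev_fraction"),
                              baseline_log_mean = NULL, baseline_log_sd = NULL,
                              dispersion = NULL, neg_mean = NULL,
                              spike_mean = 2000, spike_dispersion = 0.01,
                              sample_scale_sd = 0.1,
                              n_de = 0L, fold_range = c(1.1, 3),
                              outlier_rate = 0, outlier_multiplier = 8,
                              seed = 1L) {
  fraction_profile <- match.arg(fraction_profile)
  prof <- if (fraction_profile == "cell_fraction") {
    list(baseline_log_mean = 7.0, baseline_log_sd = 1.2,
         dispersion = 0.12, neg_mean = 40)
  } else {
    list(baseline_log_mean = 4.8, baseline_log_sd = 1.6,
         dispersion = 0.30, neg_mean = 10)
  }
  if (is.null(baseline_log_mean)) baseline_log_mean <- prof$baseline_log_mean
  if (is.null(baseline_log_sd)) baseline_log_sd <- prof$baseline_log_sd
  if (is.null(dispersion)) dispersion <- prof$dispersion
  if (is.null(neg_mean)) neg_mean <- prof$neg_mean

  cfg <- list(n_endogenous = as.integer(n_endogenous),
              n_negative = as.integer(n_negative),
              n_spikein = as.integer(n_spikein),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              fraction_profile = fraction_profile,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion = dispersion, neg_mean = neg_mean,
              spike_mean = spike_mean, spike_dispersion = spike_dispersion,
              sample_scale_sd = sample_scale_sd,
              n_de = as.integer(n_de), fold_range = as.numeric(fold_range),
              outlier_rate = outlier_rate,
              outlier_multiplier = outlier_multiplier,
              seed = as.integer(seed))
  if (cfg$n_de > cfg$n_endogenous)
    stop("n_de cannot exceed n_endogenous", call. = FALSE)
  if (length(cfg$fold_range) != 2 || any(cfg$fold_range <= 1) ||
      cfg$fold_range[1] > cfg$fold_range[2])
    stop("fold_range must be an increasing pair of reals > 1", call. = FALSE)
  if (cfg$dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1)
    stop("outlier_rate must lie in [0, 1]", call. = FALSE)
  with(cfg, stopifnot(n_endogenous >= 0, n_negative >= 0, n_spikein >= 0,
                      n_case >= 0, n_control >= 0))
  structure(cfg, class = "simulation_config")
}

rnb <- function(n, mu, phi) stats::rnbinom(n, mu = mu, size = 1 / phi)

#' Simulate a two-group NanoString-style count panel with known ground truth
#'
#' @param config a [simulation_config()].
#' @return list with elements `matrix` (a `count_matrix`) and `truth` (class
#'   `ground_truth`: data.frame `de_probes` with `probe_id`, `direction`,
#'   `fold`; data.frame `outlier_cells`; the seed). Deterministic given
#'   `config$seed`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(op_seed(config$seed, "simulate_counts"))

  endo_id <- sprintf("hsa-miR-sim-%04d", seq_len(config$n_endogenous))
  neg_id <- sprintf("NEG_%02d", seq_len(config$n_negative))
  spike_id <- sprintf("spikein-osa-miR-%02d", seq_len(config$n_spikein))
  probes <- data.frame(
    probe_id = c(endo_id, neg_id, spike_id),
    code_class = rep(c("Endogenous", "Negative", "SpikeIn"),
                     c(config$n_endogenous, config$n_negative, config$n_spikein)),
    accession = "",
    stringsAsFactors = FALSE
  )

  n_samp <- config$n_case + config$n_control
  sample_id <- c(sprintf("CASE_%02d", seq_len(config$n_case)),
                 sprintf("CTRL_%02d", seq_len(config$n_control)))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  samples <- data.frame(sample_id = sample_id, group = group,
                        fraction = config$fraction_profile,
                        rin = round(stats::runif(n_samp, 7.5, 9.8), 1),
                        stringsAsFactors = FALSE)

  ## per-probe baseline means (log-normal), drawn independently of group sizes
  base_mu <- exp(stats::rnorm(config$n_endogenous, config$baseline_log_mean,
                              config$baseline_log_sd))
  ## per-sample technical scale factors (lane effects)
  scale_f <- exp(stats::rnorm(n_samp, 0, config$sample_scale_sd))

  ## planted DE probes: random subset, random direction, fold ~ U(fold_range)
  de_probes <- data.frame(probe_id = character(0), direction = character(0),
                          fold = numeric(0), stringsAsFactors = FALSE)
  fold_mult <- rep(1, config$n_endogenous) # multiplier on CASE means
  if (config$n_de > 0) {
    de_idx <- sort(sample.int(config$n_endogenous, config$n_de))
    dir <- sample(c("up", "down"), config$n_de, replace = TRUE)
    fold <- stats::runif(config$n_de, config$fold_range[1], config$fold_range[2])
    fold_mult[de_idx] <- ifelse(dir == "up", fold, 1 / fold)
    de_probes <- data.frame(probe_id = endo_id[de_idx], direction = dir,
                            fold = fold, stringsAsFactors = FALSE)
  }

  is_case <- group == "case"
  mu_endo <- outer(base_mu, scale_f)
  mu_endo[, is_case] <- mu_endo[, is_case] * fold_mult
  endo <- matrix(rnb(length(mu_endo), mu_endo, config$dispersion),
                 config$n_endogenous, n_samp)

  ## negative ligation controls: low-mean, group-independent, no lane scaling
  ## (background is dominated by chemistry, not input)
  neg <- matrix(rnb(config$n_negative * n_samp, config$neg_mean,
                    config$dispersion),
                config$n_negative, n_samp)

  ## spike-ins: fixed input amount, low biological variance, lane scale only
  mu_spike <- outer(rep(config$spike_mean, config$n_spikein), scale_f)
  spike <- matrix(rnb(length(mu_spike), mu_spike, config$spike_dispersion),
                  config$n_spikein, n_samp)

  counts <- rbind(endo, neg, spike)
  dimnames(counts) <- list(probes$probe_id, sample_id)

  truth <- structure(list(de_probes = de_probes,
                          outlier_cells = data.frame(probe_id = character(0),
                                                     sample_id = character(0),
                                                     stringsAsFactors = FALSE),
                          seed = config$seed),
                     class = "ground_truth")
  out <- list(matrix = count_matrix(counts, probes, samples), truth = truth)
  if (config$outlier_rate > 0)
    out <- inject_outliers(out$matrix, out$truth, config$outlier_rate,
                           config$outlier_multiplier, config$seed)
  out
}

#' Inject multiplicative outlier values into a count matrix
#'
#' A Bernoulli(`rate`) selection of probe x sample cells is multiplied by
#' `multiplier` (rounded to integer). Outliers are multiplicative so they
#' survive normalization, as real flier counts do. Selected cells are recorded
#' in the ground truth.
#'
#' @param matrix a `count_matrix`.
#' @param truth a `ground_truth` (its `outlier_cells` gets extended).
#' @param rate probability in `[0, 1]` that a cell becomes an outlier.
#' @param multiplier factor > 1 applied to selected cells.
#' @param seed integer seed; deterministic given it.
#' @return list with updated `matrix` and `truth`.
#' @export
inject_outliers <- function(matrix, truth, rate, multiplier, seed) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  if (multiplier <= 1) stop("multiplier must be > 1", call. = FALSE)
  set.seed(op_seed(seed, "inject_outliers"))
  sel <- stats::runif(length(matrix$counts)) < rate
  counts <- matrix$counts
  counts[sel] <- as.integer(round(as.numeric(counts[sel]) * multiplier))
  idx <- which(matrix(sel, nrow(counts), ncol(counts)), arr.ind = TRUE)
  cells <- data.frame(probe_id = rownames(counts)[idx[, 1]],
                      sample_id = colnames(counts)[idx[, 2]],
                      stringsAsFactors = FALSE)
  truth$outlier_cells <- rbind(truth$outlier_cells, cells)
  list(matrix = count_matrix(counts, matrix$probes, matrix$samples),
       truth = truth)
}
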