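#' @keywords internal
"_PACKAGE"

## Valid probe classes on an nCounter miRNA codeset, and the case-insensitive
## aliases under which vendors/exports spell them. "Ligation" probes are the
## negative ligation controls whose counts estimate background.
CODE_CLASSES <- c("Endogenous", "Negative", "Positive", "SpikeIn", "Housekeeping")

CODE_CLASS_ALIASES <- c(
  endogenous   = "Endogenous",
  endogenous1  = "Endogenous",
  negative     = "Negative",
  ligation     = "Negative",
  positive     = "Positive",
  spikein      = "SpikeIn",
  "spike-in"   = "SpikeIn",
  spike_in     = "SpikeIn",
  housekeeping = "Housekeeping"
)

GROUPS <- c("case", "control")

FRACTIONS <- c("cell_fraction", "ev_fraction")

FRACTION_ALIASES <- c(
  cell_fraction = "cell_fraction",
  pbmc          = "cell_fraction",
  cell          = "cell_fraction",
  ev_fraction   = "ev_fraction",
  ev            = "ev_fraction",
  plasma_ev     = "ev_fraction"
)

#' Normalize a probe code-class label
#'
#' Maps vendor spellings (case-insensitive; e.g. `"Spike-In"`, `"Ligation"`)
#' onto the five canonical classes `Endogenous`, `Negative`, `Positive`,
#' `SpikeIn`, `Housekeeping`. Unknown classes are an error rather than being
#' guessed at.
#'
#' @param x character vector of raw code-class labels.
#' @return character vector of canonical class names.
#' @export
normalize_code_class <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- CODE_CLASS_ALIASES[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown probe code class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

normalize_fraction <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- FRACTION_ALIASES[key]
  if (anyNA(out)) {
    stop("unknown fraction label(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

#' Construct a probe-by-sample count matrix container
#'
#' The universal currency of the pipeline: an integer probes x samples grid
#' together with probe annotations (code class per probe) and a sample sheet
#' (group, fraction, optional RIN per sample).
#'
#' @param counts integer matrix, probes in rows, samples in columns, with
#'   dimnames matching `probes$probe_id` and `samples$sample_id`.
#' @param probes data.frame with columns `probe_id`, `code_class` and
#'   optionally `accession`.
#' @param samples data.frame with columns `sample_id`, `group`
#'   (`case`/`control`), `fraction` (`cell_fraction`/`ev_fraction`) and
#'   optionally `rin` (0-10 or `NA`).
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, probes, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(is.na(counts))) stop("counts contain NA", call. = FALSE)
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (any(counts != floor(counts)))
    stop("non-integer counts are not allowed (raw nCounter output is integral)",
         call. = FALSE)
  storage.mode(counts) <- "integer"

  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "code_class") %in% names(probes)))
    stop("probes must have columns probe_id and code_class", call. = FALSE)
  if (is.null(probes$accession)) probes$accession <- rep("", nrow(probes))
  probes$code_class <- normalize_code_class(probes$code_class)
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id in panel annotation", call. = FALSE)

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples))
    stop("samples must have a sample_id column", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  if (!is.null(samples$group)) {
    samples$group <- tolower(as.character(samples$group))
    if (!all(samples$group %in% GROUPS))
      stop("sample group must be one of: ", paste(GROUPS, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(samples$fraction)) {
    samples$fraction <- normalize_fraction(samples$fraction)
  }
  if (is.null(samples$rin)) samples$rin <- NA_real_
  samples$rin <- as.numeric(samples$rin)
  if (any(!is.na(samples$rin) & (samples$rin < 0 | samples$rin > 10)))
    stop("RIN values must lie in [0, 10]", call. = FALSE)

  if (nrow(counts) != nrow(probes) || ncol(counts) != nrow(samples))
    stop("count grid dimensions do not match annotations/sample sheet",
         call. = FALSE)
  dimnames(counts) <- list(probes$probe_id, samples$sample_id)

  structure(list(counts = counts, probes = probes, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cls <- table(factor(x$probes$code_class, levels = CODE_CLASSES))
  cat("count_matrix: ", nrow(x$counts), " probes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
      "\n")
  if (!is.null(x$samples$group))
    cat("  groups:",
        paste(sprintf("%s=%d", names(table(x$samples$group)),
                      as.integer(table(x$samples$group))), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by probes and/or samples
#'
#' @param x a `count_matrix`.
#' @param probes character vector of probe ids to keep (default all).
#' @param samples character vector of sample ids to keep (default all).
#' @return a `count_matrix` restricted to the requested ids, in the order given.
#' @export
subset_count_matrix <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  pid <- if (is.null(probes)) x$probes$probe_id else probes
  sid <- if (is.null(samples)) x$samples$sample_id else samples
  if (!all(pid %in% x$probes$probe_id)) stop("unknown probe id", call. = FALSE)
  if (!all(sid %in% x$samples$sample_id)) stop("unknown sample id", call. = FALSE)
  count_matrix(
    x$counts[pid, sid, drop = FALSE],
    x$probes[match(pid, x$probes$probe_id), , drop = FALSE],
    x$samples[match(sid, x$samples$sample_id), , drop = FALSE]
  )
}

#' Probe ids of a given code class
#'
#' @param x a `count_matrix`.
#' @param class one of `Endogenous`, `Negative`, `Positive`, `SpikeIn`,
#'   `Housekeeping`.
#' @return character vector of probe ids.
#' @export
probes_of_class <- function(x, class) {
  stopifnot(inherits(x, "count_matrix"))
  class <- match.arg(class, CODE_CLASSES)
  x$probes$probe_id[x$probes$code_class == class]
}

#' Named group vector for a count matrix
#'
#' @param x a `count_matrix` whose sample sheet carries a `group` column.
#' @return named character vector mapping sample_id to `case`/`control`.
#' @export
sample_groups <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(x$samples$group)) stop("sample sheet has no group column", call. = FALSE)
  stats::setNames(x$samples$group, x$samples$sample_id)
}
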