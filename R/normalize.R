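#' Geometric mean with platform-style zero replacement
#'
#' Zeros are replaced by 1 before taking logs (the digital-count platform
#' convention), so the geometric mean of a vector containing zeros is finite.
#'
#' @param x non-negative numeric vector.
#' @param zero_value replacement for exact zeros (default 1).
#' @return the geometric mean.
#' @export
geomean <- function(x, zero_value = 1) {
  if (length(x) == 0) stop("geomean of empty vector", call. = FALSE)
  if (any(x < 0)) stop("geomean requires non-negative values", call. = FALSE)
  x[x == 0] <- zero_value
  exp(mean(log(x)))
}

#' Background threshold from negative ligation controls
#'
#' Pools the counts of all Negative-class probes across every sample of the
#' fraction and returns their geometric mean plus `n_sd` sample standard
#' deviations. Counts below this value are treated as background. One pooled
#' threshold is computed per fraction, not per sample.
#'
#' @param matrix a `count_matrix` for one fraction.
#' @param n_sd number of standard deviations above the geometric mean
#'   (default 2).
#' @return list of class `threshold_result` with `threshold`, `neg_geomean`,
#'   `neg_sd` (sample SD, n-1 denominator, computed on the unreplaced pooled
#'   counts) and `n_values`.
#' @export
background_threshold <- function(matrix, n_sd = 2) {
  stopifnot(inherits(matrix, "count_matrix"))
  neg <- probes_of_class(matrix, "Negative")
  if (length(neg) == 0)
    stop("no Negative-class probes in panel; cannot set background threshold",
         call. = FALSE)
  pooled <- as.vector(matrix$counts[neg, , drop = FALSE])
  if (length(pooled) < 2)
    stop("need at least 2 pooled negative-control values", call. = FALSE)
  g <- geomean(pooled)
  s <- stats::sd(pooled)
  structure(list(threshold = g + n_sd * s, neg_geomean = g, neg_sd = s,
                 n_values = length(pooled)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "background threshold: %.2f counts (geomean %.2f + 2 x SD %.2f, n = %d)\n",
    x$threshold, x$neg_geomean, x$neg_sd, x$n_values))
  invisible(x)
}

#' Per-sample normalization factors from a reference probe set
#'
#' The reference set is either the `n` endogenous probes with the highest mean
#' raw count across samples (`top_n`; ties broken by lexicographic probe id) or
#' the panel's spike-in probes (`spikein`). Each sample's factor is the ratio
#' of the across-sample arithmetic mean of reference geometric means to that
#' sample's reference geometric mean, so that after scaling every sample's
#' reference geometric mean is equal.
#'
#' @param matrix a `count_matrix`.
#' @param reference `"top_n"` or `"spikein"`.
#' @param n reference-set size for `top_n` (default 100).
#' @return named numeric vector of factors (> 0), one per sample, with the
#'   reference probe ids in attribute `"reference_probes"`.
#' @export
reference_factors <- function(matrix, reference = c("top_n", "spikein"),
                              n = 100) {
  stopifnot(inherits(matrix, "count_matrix"))
  reference <- match.arg(reference)
  if (reference == "top_n") {
    endo <- probes_of_class(matrix, "Endogenous")
    if (length(endo) < n)
      stop("top_n reference needs at least ", n, " endogenous probes",
           call. = FALSE)
    m <- rowMeans(matrix$counts[endo, , drop = FALSE])
    ref <- endo[order(-m, endo)][seq_len(n)]
  } else {
    ref <- probes_of_class(matrix, "SpikeIn")
    if (length(ref) == 0)
      stop("spikein reference requested but panel has no SpikeIn probes",
           call. = FALSE)
  }
  g <- apply(matrix$counts[ref, , drop = FALSE], 2, geomean)
  factors <- mean(g) / g
  attr(factors, "reference_probes") <- ref
  attr(factors, "reference") <- reference
  factors
}

#' Apply normalization factors and background censoring
#'
#' Every cell becomes `raw count x factor`. Cells whose RAW count lies strictly
#' below the background threshold are flagged non-detected; the censoring mask
#' travels with the matrix (values are retained for inspection but excluded
#' from downstream statistics).
#'
#' @param matrix a `count_matrix`.
#' @param factors named factor vector from [reference_factors()] (must cover
#'   all samples).
#' @param threshold a `threshold_result` or a single number.
#' @return list of class `normalized_matrix` with `values`, `detected`
#'   (logical grid: raw >= threshold), `factors`, `threshold`, `reference`,
#'   `probes`, `samples` and the raw `counts`.
#' @export
apply_normalization <- function(matrix, factors, threshold) {
  stopifnot(inherits(matrix, "count_matrix"))
  sid <- matrix$samples$sample_id
  if (!all(sid %in% names(factors)))
    stop("missing normalization factor for sample(s): ",
         paste(setdiff(sid, names(factors)), collapse = ", "), call. = FALSE)
  if (any(factors[sid] <= 0)) stop("factors must be > 0", call. = FALSE)
  thr <- if (inherits(threshold, "threshold_result")) threshold$threshold
         else as.numeric(threshold)
  values <- sweep(matrix$counts + 0, 2, factors[sid], `*`)
  detected <- matrix$counts >= thr
  structure(list(values = values, detected = detected,
                 factors = factors[sid],
                 threshold = if (inherits(threshold, "threshold_result"))
                   threshold else
                   structure(list(threshold = thr, neg_geomean = NA_real_,
                                  neg_sd = NA_real_, n_values = NA_integer_),
                             class = "threshold_result"),
                 reference = attr(factors, "reference"),
                 probes = matrix$probes, samples = matrix$samples,
                 counts = matrix$counts),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples\n", sep = "")
  cat(sprintf("  threshold %.2f; %.1f%% of cells detected\n",
              x$threshold$threshold, 100 * mean(x$detected)))
  invisible(x)
}
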