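filter_log_entry <- function(stage, removed_ids, criterion, parameters,
                             n_before, n_after) {
  list(stage = stage, removed_ids = as.character(removed_ids),
       criterion = criterion, parameters = parameters,
       n_before = n_before, n_after = n_after)
}

#' Detection mask of a normalized matrix
#'
#' @param norm a `normalized_matrix`.
#' @param endogenous_only restrict rows to Endogenous probes (default `TRUE`;
#'   detection bookkeeping concerns the measured miRNAs, not control probes).
#' @return list of class `detection_mask` with `detected` (logical probes x
#'   samples grid, `TRUE` iff raw count >= threshold) and `threshold`.
#' @export
detection_mask <- function(norm, endogenous_only = TRUE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  det <- norm$detected
  if (endogenous_only) {
    endo <- norm$probes$probe_id[norm$probes$code_class == "Endogenous"]
    det <- det[endo, , drop = FALSE]
  }
  structure(list(detected = det, threshold = norm$threshold$threshold),
            class = "detection_mask")
}

#' RIN quality gate for cellular-fraction samples
#'
#' Keeps samples whose RNA Integrity Number is strictly above `min_rin`.
#' EV-fraction samples pass unconditionally: no RIN-style quality control is
#' applicable to total RNA from extracellular vesicles. A cell-fraction
#' sample with a missing RIN is an integrity error.
#'
#' @param samples sample sheet data.frame (`sample_id`, `fraction`, `rin`).
#' @param min_rin exclusive lower bound (default 7).
#' @return list with `kept` (sample ids) and `log` (a filter-log entry).
#' @export
filter_by_rin <- function(samples, min_rin = 7.0) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  fraction <- if (is.null(samples$fraction)) rep("cell_fraction", nrow(samples))
              else normalize_fraction(samples$fraction)
  rin <- if (is.null(samples$rin)) rep(NA_real_, nrow(samples))
         else as.numeric(samples$rin)
  cellular <- fraction == "cell_fraction"
  if (any(cellular & is.na(rin)))
    stop("missing RIN for cell-fraction sample(s): ",
         paste(samples$sample_id[cellular & is.na(rin)], collapse = ", "),
         call. = FALSE)
  keep <- !cellular | (rin > min_rin)
  list(kept = samples$sample_id[keep],
       log = filter_log_entry("rin_gate", samples$sample_id[!keep],
                              sprintf("RIN > %g (cell fraction only)", min_rin),
                              list(min_rin = min_rin),
                              nrow(samples), sum(keep)))
}

#' Remove samples with poor panel-wide detection
#'
#' A sample is removed when the fraction of (endogenous) probes below the
#' background threshold is `max_below_frac` or more (boundary inclusive).
#'
#' @param mask a `detection_mask`.
#' @param max_below_frac removal boundary (default 0.40).
#' @return list with `kept` (sample ids) and `log`.
#' @export
drop_low_coverage_samples <- function(mask, max_below_frac = 0.40) {
  stopifnot(inherits(mask, "detection_mask"))
  if (nrow(mask$detected) == 0)
    stop("detection mask has zero probes", call. = FALSE)
  frac_below <- colMeans(!mask$detected)
  keep <- frac_below < max_below_frac
  list(kept = colnames(mask$detected)[keep],
       log = filter_log_entry("low_coverage_samples",
                              colnames(mask$detected)[!keep],
                              sprintf("below-threshold fraction >= %g",
                                      max_below_frac),
                              list(max_below_frac = max_below_frac,
                                   probe_universe = nrow(mask$detected)),
                              ncol(mask$detected), sum(keep)))
}

#' Keep probes robustly detected in at least one group
#'
#' A probe is retained when its detected fraction reaches `min_frac`
#' (inclusive) in the case group OR in the control group.
#'
#' @param mask a `detection_mask` (columns = samples under analysis).
#' @param groups named character vector sample_id -> `case`/`control`.
#' @param min_frac detection fraction boundary (default 0.75).
#' @return list with `kept` (probe ids) and `log`.
#' @export
robust_probe_filter <- function(mask, groups, min_frac = 0.75) {
  stopifnot(inherits(mask, "detection_mask"))
  sid <- colnames(mask$detected)
  groups <- groups[sid]
  if (anyNA(groups)) stop("groups must cover every sample in the mask", call. = FALSE)
  for (g in GROUPS)
    if (!any(groups == g)) stop("group '", g, "' has no samples", call. = FALSE)
  frac <- function(g)
    rowMeans(mask$detected[, groups == g, drop = FALSE])
  keep <- frac("case") >= min_frac | frac("control") >= min_frac
  list(kept = rownames(mask$detected)[keep],
       log = filter_log_entry("robust_probes", rownames(mask$detected)[!keep],
                              sprintf("detected in >= %g of either group",
                                      min_frac),
                              list(min_frac = min_frac),
                              nrow(mask$detected), sum(keep)))
}

#' Single-pass 2-SD band outlier rejection (Chauvenet-style)
#'
#' Computes the mean and sample standard deviation of the input once and
#' removes values lying strictly outside the band mean +/- `n_sd` x SD. No
#' re-iteration after removal. With fewer than 3 values, or a zero SD, nothing
#' is removed. An optional retention floor (`min_keep`) limits how many values
#' may be removed: the most extreme values go first and removal stops at the
#' floor.
#'
#' @param values numeric vector.
#' @param n_sd half-width of the acceptance band in SD units (default 2).
#' @param min_keep minimum number of values that must survive (default 0 =
#'   no floor; the differential-expression stage applies its own per-group
#'   floor).
#' @return list with `kept` (values, input order preserved) and `removed`
#'   (integer indices into the input, ascending).
#' @export
chauvenet_filter <- function(values, n_sd = 2, min_keep = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) return(list(kept = values, removed = integer(0)))
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(list(kept = values, removed = integer(0)))
  dev <- abs(values - m)
  out <- which(dev > n_sd * s)
  allowed <- max(0L, n - as.integer(min_keep))
  if (length(out) > allowed) {
    ## keep the least extreme offenders: remove by descending deviation,
    ## ties resolved by earlier index first (deterministic)
    out <- out[order(-dev[out], out)][seq_len(allowed)]
  }
  out <- sort(out)
  list(kept = if (length(out)) values[-out] else values, removed = out)
}
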