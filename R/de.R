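#' Normality-branched two-group comparison
#'
#' Branch rule: each group is screened with the Shapiro-Wilk test; when BOTH
#' groups look normal (Shapiro p > `shapiro_alpha`), the groups are compared
#' with a two-sided equal-variance Student's t test, otherwise with a
#' two-sided Mann-Whitney test (exact distribution when both n <= 15 and
#' there are no ties; normal approximation with continuity and tie correction
#' otherwise). The screen requires at least `shapiro_min_n` (default 4)
#' values per group: Shapiro-Wilk has essentially no power at n = 3 (three
#' points can almost never contradict normality), so smaller groups default
#' to the rank test. Two significance tiers are reported: `significant`
#' (p < `p_sig`) and `trend` (`p_sig` <= p < `p_trend`).
#'
#' Direction and percent change use group means under the t branch and group
#' medians under the Mann-Whitney branch.
#'
#' @param case,control numeric vectors (each length >= 2).
#' @param p_sig,p_trend tier boundaries (defaults 0.05 and 0.1).
#' @param shapiro_alpha normality screen level (default 0.05).
#' @param var_equal use the classical equal-variance t statistic
#'   (default `TRUE`); set `FALSE` for Welch.
#' @param both_groups_normal require BOTH groups to pass the normality screen
#'   for the t branch (default `TRUE`, the conservative reading).
#' @param exact_max_n largest per-group n for the exact Mann-Whitney
#'   distribution (default 15).
#' @param shapiro_min_n smallest per-group n at which the normality screen is
#'   consulted (default 4).
#' @param force_test bypass the normality screen and use the given branch
#'   (`"t_student"` or `"mann_whitney"`); used when re-testing
#'   outlier-adjusted values with the branch chosen on the full data.
#' @return list of class `group_compare` with `n_case`, `n_control`, `test`
#'   (`t_student`/`mann_whitney`), `statistic`, `p`, `direction`
#'   (`up`/`down`/`none`, case relative to control), `pct_change`, `tier`,
#'   and the location summaries used.
#' @export
shapiro_branch_test <- function(case, control, p_sig = 0.05, p_trend = 0.1,
                                shapiro_alpha = 0.05, var_equal = TRUE,
                                both_groups_normal = TRUE, exact_max_n = 15,
                                shapiro_min_n = 4, force_test = NULL) {
  case <- as.numeric(case); control <- as.numeric(control)
  if (length(case) < 2 || length(control) < 2)
    stop("each group needs at least 2 values", call. = FALSE)

  normal_p <- function(x) {
    if (length(x) < shapiro_min_n) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  pa <- normal_p(case); pb <- normal_p(control)
  ok <- function(p) !is.na(p) && p > shapiro_alpha
  use_t <- if (both_groups_normal) ok(pa) && ok(pb) else ok(pa) || ok(pb)
  if (!is.null(force_test))
    use_t <- match.arg(force_test, c("t_student", "mann_whitney")) == "t_student"

  ## two unequal constants: t is undefined (zero pooled variance), rank test
  ## handles it
  if (use_t && stats::sd(case) == 0 && stats::sd(control) == 0)
    use_t <- FALSE

  degenerate <- length(unique(c(case, control))) == 1
  if (degenerate) {
    test <- "mann_whitney"; statistic <- NA_real_; p <- 1
    cs <- stats::median(case); ctl <- stats::median(control)
  } else if (use_t) {
    tt <- stats::t.test(case, control, var.equal = var_equal)
    test <- "t_student"
    statistic <- unname(tt$statistic); p <- tt$p.value
    cs <- mean(case); ctl <- mean(control)
  } else {
    ties <- anyDuplicated(c(case, control)) > 0
    exact <- length(case) <= exact_max_n && length(control) <= exact_max_n &&
      !ties
    wt <- suppressWarnings(stats::wilcox.test(case, control, exact = exact,
                                              correct = TRUE))
    test <- "mann_whitney"
    statistic <- unname(wt$statistic); p <- wt$p.value
    cs <- stats::median(case); ctl <- stats::median(control)
  }

  direction <- if (cs > ctl) "up" else if (cs < ctl) "down" else "none"
  pct <- if (direction == "none") 0 else
    tryCatch(percent_change(cs, ctl, direction), error = function(e) NA_real_)
  tier <- if (p < p_sig) "significant" else if (p < p_trend) "trend" else "ns"

  structure(list(n_case = length(case), n_control = length(control),
                 test = test, statistic = statistic, p = p,
                 direction = direction, pct_change = pct, tier = tier,
                 case_summary = cs, control_summary = ctl,
                 shapiro_p_case = pa, shapiro_p_control = pb),
            class = "group_compare")
}

#' @export
print.group_compare <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, p = %.4g [%s], direction %s, change %.1f%% (n = %d/%d)\n",
              x$test, x$statistic, x$p, x$tier, x$direction, x$pct_change,
              x$n_case, x$n_control))
  invisible(x)
}

#' Asymmetric percent change between group summaries
#'
#' Over-expression is expressed relative to the control level,
#' `100 (case - control) / control`; under-expression relative to the case
#' level, `100 (control - case) / case`. The asymmetric convention lets
#' under-expression exceed 100%.
#'
#' @param case_summary,control_summary positive location summaries.
#' @param direction `"up"` or `"down"`.
#' @return percent change (non-negative for summaries consistent with
#'   `direction`).
#' @export
percent_change <- function(case_summary, control_summary,
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  denom <- if (direction == "up") control_summary else case_summary
  if (!is.finite(denom) || denom == 0)
    stop("percent change undefined: zero denominator", call. = FALSE)
  if (direction == "up") 100 * (case_summary - control_summary) / control_summary
  else 100 * (control_summary - case_summary) / case_summary
}

#' Differential expression over the robust probe set
#'
#' For each probe the per-probe sample universe is the set of samples in which
#' the probe is detected (raw count at or above the background threshold), so
#' per-group n varies by probe. Each probe gets a first-pass
#' [shapiro_branch_test()]; probes whose first-pass p falls below `p_trend`
#' are re-tested after a per-group [chauvenet_filter()] outlier adjustment
#' (with a retention floor of `chauvenet_min_keep` values per group), and the
#' adjusted result is reported. Probes never reaching `p_trend` are reported
#' unadjusted. Probes whose per-group n drops below 2 are excluded and logged.
#'
#' A Benjamini-Hochberg column (`p_bh`) is emitted as supplementary output;
#' tiers are driven by the unadjusted p values, as is conventional for this
#' two-tier screening design.
#'
#' @param norm a `normalized_matrix`.
#' @param probes character vector: the robust probe set to test.
#' @param groups named character vector sample_id -> `case`/`control`; its
#'   names define the samples under analysis.
#' @param p_sig,p_trend tier boundaries.
#' @param chauvenet apply the outlier adjustment to candidate probes
#'   (default `TRUE`).
#' @param chauvenet_sd band half-width in SD units (default 2).
#' @param chauvenet_min_keep per-group retention floor (default 10; 0
#'   disables).
#' @param ... further arguments passed to [shapiro_branch_test()].
#' @return a `de_table`: data.frame sorted by ascending p with columns
#'   `probe_id`, `n_case`, `n_control`, `test`, `statistic`, `p`, `p_bh`,
#'   `direction`, `pct_change`, `tier`, `removed_case`, `removed_control`.
#'   Attributes: `excluded` (filter-log entry), `values` (per-probe final
#'   case/control vectors, for ROC and plotting).
#' @export
run_de <- function(norm, probes, groups, p_sig = 0.05, p_trend = 0.1,
                   chauvenet = TRUE, chauvenet_sd = 2,
                   chauvenet_min_keep = 10, ...) {
  stopifnot(inherits(norm, "normalized_matrix"))
  sid <- names(groups)
  if (!all(sid %in% colnames(norm$values)))
    stop("groups reference samples absent from the matrix", call. = FALSE)
  if (!all(probes %in% rownames(norm$values)))
    stop("robust set references unknown probes", call. = FALSE)

  rows <- list(); vals <- list(); excluded <- character(0)
  for (p in probes) {
    det <- norm$detected[p, sid]
    case_v <- norm$values[p, sid[groups == "case" & det]]
    ctl_v <- norm$values[p, sid[groups == "control" & det]]
    if (length(case_v) < 2 || length(ctl_v) < 2) {
      excluded <- c(excluded, p)
      next
    }
    first <- shapiro_branch_test(case_v, ctl_v, p_sig = p_sig,
                                 p_trend = p_trend, ...)
    removed_case <- 0L; removed_control <- 0L
    res <- first
    if (chauvenet && first$p < p_trend) {
      cf_case <- chauvenet_filter(case_v, n_sd = chauvenet_sd,
                                  min_keep = chauvenet_min_keep)
      cf_ctl <- chauvenet_filter(ctl_v, n_sd = chauvenet_sd,
                                 min_keep = chauvenet_min_keep)
      removed_case <- length(cf_case$removed)
      removed_control <- length(cf_ctl$removed)
      if ((removed_case || removed_control) &&
          length(cf_case$kept) >= 2 && length(cf_ctl$kept) >= 2) {
        ## the branch is decided once, on the full detected data; the
        ## adjustment refines values, not the distributional call
        res <- shapiro_branch_test(cf_case$kept, cf_ctl$kept, p_sig = p_sig,
                                   p_trend = p_trend,
                                   force_test = first$test, ...)
        case_v <- cf_case$kept; ctl_v <- cf_ctl$kept
      } else {
        removed_case <- 0L; removed_control <- 0L
      }
    }
    rows[[p]] <- data.frame(probe_id = p, n_case = res$n_case,
                            n_control = res$n_control, test = res$test,
                            statistic = res$statistic, p = res$p,
                            direction = res$direction,
                            pct_change = res$pct_change, tier = res$tier,
                            removed_case = removed_case,
                            removed_control = removed_control,
                            stringsAsFactors = FALSE)
    vals[[p]] <- list(case = unname(case_v), control = unname(ctl_v))
  }

  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(0), n_case = integer(0),
               n_control = integer(0), test = character(0),
               statistic = numeric(0), p = numeric(0),
               direction = character(0), pct_change = numeric(0),
               tier = character(0), removed_case = integer(0),
               removed_control = integer(0), stringsAsFactors = FALSE)
  tab$p_bh <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$probe_id),
             c("probe_id", "n_case", "n_control", "test", "statistic", "p",
               "p_bh", "direction", "pct_change", "tier", "removed_case",
               "removed_control")]
  rownames(tab) <- NULL
  attr(tab, "excluded") <- filter_log_entry(
    "de_low_n", excluded, "per-group n >= 2 after detection censoring",
    list(), length(probes), nrow(tab))
  attr(tab, "values") <- vals
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' Venn partition of two detected-probe sets over a panel universe
#'
#' @param set_a,set_b character vectors of probe ids (e.g. the robust sets of
#'   the two blood fractions).
#' @param universe_size total number of probes in the panel.
#' @return list of class `venn_partition` with `shared`, `exclusive_a`,
#'   `exclusive_b`, `neither`, `universe`; the four components always sum to
#'   the universe.
#' @export
venn_partition <- function(set_a, set_b, universe_size) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  union_n <- length(union(set_a, set_b))
  if (union_n > universe_size)
    stop("universe smaller than the union of the two sets", call. = FALSE)
  shared <- length(intersect(set_a, set_b))
  structure(list(shared = shared,
                 exclusive_a = length(set_a) - shared,
                 exclusive_b = length(set_b) - shared,
                 neither = universe_size - union_n,
                 universe = universe_size),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn: shared %d | exclusive A %d | exclusive B %d | neither %d (universe %d)\n",
              x$shared, x$exclusive_a, x$exclusive_b, x$neither, x$universe))
  invisible(x)
}
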