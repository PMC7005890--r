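#' Empirical AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney U statistic divided by `n_case x n_control`
#' (tied pairs count 1/2), computed by midrank arithmetic. Orientation is
#' auto-selected so the reported AUC is at least 0.5: `case_high` when cases
#' tend to have higher values, `case_low` otherwise. The confidence interval
#' uses the DeLong placement-value variance estimator, truncated to `[0, 1]`.
#'
#' @param values numeric marker values.
#' @param labels vector of `"case"` / `"control"`, same length.
#' @param alpha two-sided error level for the CI (default 0.05 -> 95% CI).
#' @param variable_id optional id carried into the result.
#' @return list of class `roc_result` with `auc`, `ci_low`, `ci_high`,
#'   `orientation`, `n_case`, `n_control`, `variable_id`.
#' @export
roc_auc_ci <- function(values, labels, alpha = 0.05, variable_id = NA_character_) {
  values <- as.numeric(values)
  labels <- as.character(labels)
  if (length(values) != length(labels))
    stop("values and labels differ in length", call. = FALSE)
  if (!all(labels %in% GROUPS))
    stop("labels must be 'case' or 'control'", call. = FALSE)
  n1 <- sum(labels == "case"); n0 <- sum(labels == "control")
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 cases and 2 controls", call. = FALSE)

  auc_raw <- auc_pair(values[labels == "case"], values[labels == "control"])
  orientation <- if (auc_raw >= 0.5) "case_high" else "case_low"
  oriented <- if (orientation == "case_high") values else -values
  x <- oriented[labels == "case"]; y <- oriented[labels == "control"]
  auc <- auc_pair(x, y)

  ## DeLong placements: V10_i = Pr(marker of case i beats a random control),
  ## V01_j = Pr(a random case beats control j); ties count 1/2.
  v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n0, 0)
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / n1, 0)
  v <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - alpha / 2)
  ci <- auc + c(-1, 1) * z * sqrt(max(v, 0))
  ci <- pmin(pmax(ci, 0), 1)

  structure(list(variable_id = variable_id, auc = auc,
                 ci_low = ci[1], ci_high = ci[2],
                 orientation = orientation, n_case = n1, n_control = n0),
            class = "roc_result")
}

## U/(n1 n0) by midranks; exact pair-counting identity, ties count 1/2.
auc_pair <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n0 <- length(y)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4g (95%% CI %.4g-%.4g), orientation %s, n = %d/%d\n",
              x$auc, x$ci_low, x$ci_high, x$orientation, x$n_case,
              x$n_control))
  invisible(x)
}

#' Heatmap leaf order by Spearman-distance centroid-linkage clustering
#'
#' Pairwise probe distance is `1 - Spearman rank correlation` between probe
#' rows; agglomeration uses centroid linkage via the Lance-Williams update.
#' Centroid linkage over a correlation distance is mathematically improper
#' (merge heights can invert); inversions are recorded in the result rather
#' than hidden. Constant rows get distance 1 to everything, by convention,
#' with a warning.
#'
#' Leaf order comes from a recursive left-before-right traversal of the merge
#' tree with the earlier-created cluster placed left (deterministic
#' tie-break; distance ties are broken by lowest probe index).
#'
#' @param mat numeric matrix, probes in rows (>= 2), samples in columns.
#' @return list of class `leaf_order` with `order` (probe ids), `merge`
#'   (hclust-style merge matrix), `height` (merge heights), `inversions`
#'   (steps whose height is lower than the previous step's), `labels`,
#'   `constant_rows`.
#' @export
cluster_leaf_order <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 probes to cluster", call. = FALSE)
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  const <- apply(mat, 1, function(r) stats::sd(r) == 0)
  rho <- suppressWarnings(stats::cor(t(mat), method = "spearman"))
  D <- 1 - rho
  D[is.na(D)] <- 1  # constant rows: correlation undefined -> distance 1
  diag(D) <- 0
  if (any(const))
    warning("constant row(s) assigned Spearman distance 1 to all others: ",
            paste(labels[const], collapse = ", "), call. = FALSE)

  size <- rep(1L, n)
  code <- -seq_len(n)            # hclust convention: negatives = singletons
  members <- as.list(seq_len(n)) # leaf indices in traversal order
  created <- seq_len(n)          # creation rank, for the left/right tie-break
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  work <- D
  diag(work) <- Inf
  work[!active, ] <- Inf

  for (s in seq_len(n - 1)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- idx[best[1]]; j <- idx[best[2]]   # i < j by construction

    height[s] <- work[i, j]
    merge[s, ] <- sort(c(code[i], code[j]))
    left_first <- created[i] <= created[j]
    members[[i]] <- if (left_first) c(members[[i]], members[[j]])
                    else c(members[[j]], members[[i]])

    ni <- size[i]; nj <- size[j]; nij <- ni + nj
    k <- setdiff(idx, c(i, j))
    if (length(k)) {
      dnew <- (ni * work[k, i] + nj * work[k, j]) / nij -
        ni * nj * work[i, j] / nij^2
      work[k, i] <- dnew; work[i, k] <- dnew
    }
    size[i] <- nij; code[i] <- s; created[i] <- n + s
    active[j] <- FALSE
    work[j, ] <- Inf; work[, j] <- Inf
  }

  root <- which(active)
  structure(list(order = labels[members[[root]]], merge = merge,
                 height = height,
                 inversions = which(diff(height) < 0) + 1L,
                 labels = labels, constant_rows = labels[const]),
            class = "leaf_order")
}

#' @export
print.leaf_order <- function(x, ...) {
  cat("leaf order (", length(x$order), " probes): ",
      paste(utils::head(x$order, 8), collapse = ", "),
      if (length(x$order) > 8) ", ..." else "", "\n", sep = "")
  if (length(x$inversions))
    cat("  centroid-linkage inversions at merge step(s): ",
        paste(x$inversions, collapse = ", "), "\n", sep = "")
  invisible(x)
}
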