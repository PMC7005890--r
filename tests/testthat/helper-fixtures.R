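# Small in-code fixtures shared across test files.

# A toy panel: `endo` endogenous probes (rows of `counts` first), then
# `neg` negative controls and `spike` spike-ins, for `n` samples split
# case/control.
toy_panel <- function(counts, endo, neg = 0, spike = 0,
                      groups = NULL, fraction = "cell_fraction", rin = NULL) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  probes <- data.frame(
    probe_id = c(sprintf("miR-%02d", seq_len(endo)),
                 if (neg) sprintf("NEG_%d", seq_len(neg)),
                 if (spike) sprintf("SPK_%d", seq_len(spike))),
    code_class = rep(c("Endogenous", "Negative", "SpikeIn"),
                     c(endo, neg, spike)),
    stringsAsFactors = FALSE
  )
  if (is.null(groups)) groups <- rep(c("case", "control"), length.out = n)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        group = groups, fraction = fraction,
                        rin = if (is.null(rin)) NA_real_ else rin,
                        stringsAsFactors = FALSE)
  count_matrix(counts, probes, samples)
}

# Exhaustive two-sided Mann-Whitney p by label enumeration (oracle).
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- abs(u_stat(a, b) - n1 * length(b) / 2)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - n1 * (length(pooled) - n1) / 2) >= obs - 1e-12)
}

# Brute-force AUC by explicit pair counting (oracle).
auc_brute <- function(case, control) {
  s <- 0
  for (x in case) for (y in control)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(case) * length(control))
}

# Brute-force single-pass 2-SD band removal (oracle).
chauvenet_brute <- function(v, n_sd = 2) {
  if (length(v) < 3) return(integer(0))
  s <- sd(v)
  if (s == 0) return(integer(0))
  which(abs(v - mean(v)) > n_sd * s)
}
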