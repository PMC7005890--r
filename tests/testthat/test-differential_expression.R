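test_that("branch test matches enumeration and hand-arithmetic oracles", {
  # Mann-Whitney branch: {1,2,3} vs {4,5,6} is non-normal-free but tiny; the
  # exact two-sided p from label enumeration is 2/20 = 0.1
  mw <- shapiro_branch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(mw$p, 0.1)
  expect_equal(mw$tier, "ns")
  expect_equal(mw$direction, "down")

  # t branch: {1..5} vs {2..6}; pooled SD sqrt(2.5), SE 1, t = -1, df 8
  tt <- shapiro_branch_test(1:5, 2:6)
  expect_equal(tt$test, "t_student")
  expect_equal(tt$statistic, -1)
  expect_equal(tt$p, 2 * pt(-1, df = 8))
  expect_equal(tt$p, 0.3466, tolerance = 1e-4)
})

test_that("identical groups are exchangeable: p = 1, direction none", {
  res <- shapiro_branch_test(c(3, 3, 3), c(3, 3, 3))
  expect_equal(res$p, 1)
  expect_equal(res$direction, "none")
  expect_equal(res$pct_change, 0)
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(10)
  for (i in 1:20) {
    a <- rexp(8); b <- rexp(9) * 1.8
    p1 <- shapiro_branch_test(a, b)
    p2 <- shapiro_branch_test(exp(a), exp(b))
    if (p1$test == "mann_whitney" && p2$test == "mann_whitney")
      expect_equal(p1$p, p2$p)
  }
  # t branch p is invariant under common affine transforms
  set.seed(11)
  a <- rnorm(10, 5); b <- rnorm(10, 6)
  r1 <- shapiro_branch_test(a, b)
  r2 <- shapiro_branch_test(3 * a + 7, 3 * b + 7)
  expect_equal(r1$test, "t_student")
  expect_equal(r1$p, r2$p)
  expect_equal(r1$statistic, r2$statistic)
})

test_that("swapping group labels preserves p and flips direction", {
  set.seed(12)
  for (i in 1:10) {
    a <- rgamma(9, 2, 0.1); b <- rgamma(9, 2, 0.06)
    r <- shapiro_branch_test(a, b)
    s <- shapiro_branch_test(b, a)
    expect_equal(r$p, s$p)
    if (r$test == "t_student")
      expect_equal(r$statistic, -s$statistic)   # t flips sign
    else
      expect_equal(r$statistic,                 # U maps to n1 n2 - U
                   length(a) * length(b) - s$statistic)
    if (r$direction != "none")
      expect_equal(s$direction, setdiff(c("up", "down"), r$direction))
  }
})

test_that("percent change uses the asymmetric up/down convention", {
  expect_equal(percent_change(150, 100, "up"), 50)
  expect_equal(percent_change(100, 310, "down"), 210)  # can exceed 100%
  expect_equal(percent_change(100, 100, "up"), 0)
  expect_error(percent_change(5, 0, "up"), "zero denominator")
})

test_that("run_de varies per-probe n with detection and conserves removals", {
  sim <- simulate_counts(simulation_config(n_endogenous = 150, n_de = 10,
                                           fold_range = c(2, 2.5), seed = 13))
  mat <- sim$matrix
  norm <- apply_normalization(mat, reference_factors(mat, "top_n", n = 50),
                              background_threshold(mat))
  mask <- detection_mask(norm)
  groups <- sample_groups(mat)
  robust <- robust_probe_filter(mask, groups)$kept
  de <- run_de(norm, robust, groups)

  expect_s3_class(de, "de_table")
  expect_false(is.unsorted(de$p))
  expect_true(all(de$n_case >= 2 & de$n_control >= 2))
  # per-probe n + removals never exceeds the detected universe for the probe
  for (i in seq_len(nrow(de))) {
    p <- de$probe_id[i]
    det <- norm$detected[p, names(groups)]
    expect_equal(de$n_case[i] + de$removed_case[i],
                 sum(det & groups == "case"))
    expect_equal(de$n_control[i] + de$removed_control[i],
                 sum(det & groups == "control"))
  }
  # tier boundaries are consistent with p
  expect_true(all((de$tier == "significant") == (de$p < 0.05)))
  expect_true(all((de$tier == "trend") == (de$p >= 0.05 & de$p < 0.1)))

  # empty robust set -> empty table
  empty <- run_de(norm, character(0), groups)
  expect_equal(nrow(empty), 0)
})

test_that("venn partition performs exact set arithmetic over the universe", {
  a <- sprintf("p%03d", 1:91)
  b <- sprintf("p%03d", 43:192)   # overlap 49
  v <- venn_partition(a, b, 798)
  expect_equal(v$shared, 49)
  expect_equal(v$exclusive_a, 42)
  expect_equal(v$exclusive_b, 101)
  expect_equal(v$neither, 606)

  same <- venn_partition(a, a, 100)
  expect_equal(same$shared, 91)
  expect_equal(same$exclusive_a + same$exclusive_b, 0)

  # random small sets vs brute-force set operations
  set.seed(14)
  for (i in 1:25) {
    u <- sprintf("u%02d", 1:40)
    x <- sample(u, sample(0:20, 1)); y <- sample(u, sample(0:20, 1))
    v2 <- venn_partition(x, y, 40)
    expect_equal(v2$shared, length(intersect(x, y)))
    expect_equal(v2$exclusive_a, length(setdiff(x, y)))
    expect_equal(v2$exclusive_b, length(setdiff(y, x)))
    expect_equal(v2$shared + v2$exclusive_a + v2$exclusive_b + v2$neither,
                 v2$universe)
  }
  expect_error(venn_partition(letters, LETTERS, 10), "universe")
})
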