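test_that("background threshold follows the geomean + 2 SD rule", {
  # zero-variance degenerate case: threshold equals the constant
  mat <- toy_panel(matrix(10L, 3, 4), endo = 1, neg = 2)
  thr <- background_threshold(mat)
  expect_equal(thr$threshold, 10)
  expect_equal(thr$neg_sd, 0)
  expect_equal(thr$n_values, 8)

  # hand-arithmetic oracle on pooled {2, 4, 8}
  mat2 <- toy_panel(matrix(c(1L, 1L, 1L, 2L, 4L, 8L), 2, byrow = TRUE),
                    endo = 1, neg = 1)
  thr2 <- background_threshold(mat2)
  expect_equal(thr2$neg_geomean, (2 * 4 * 8)^(1 / 3))
  expect_equal(thr2$neg_sd, sd(c(2, 4, 8)))
  expect_equal(thr2$threshold, 4 + 2 * sd(c(2, 4, 8)))
  expect_equal(thr2$threshold, 10.110, tolerance = 1e-3)

  expect_error(background_threshold(toy_panel(matrix(1:4, 2), endo = 2)),
               "no Negative")
})

test_that("threshold is invariant under sample permutation and zero-safe", {
  sim <- simulate_counts(simulation_config(n_endogenous = 40, seed = 71))
  mat <- sim$matrix
  perm <- subset_count_matrix(mat, samples = rev(mat$samples$sample_id))
  expect_equal(background_threshold(mat)$threshold,
               background_threshold(perm)$threshold)

  # zeros only affect the geometric mean via the zero -> 1 replacement
  mat0 <- toy_panel(matrix(c(5L, 0L, 4L, 9L), 1, 4), endo = 0, neg = 1)
  thr <- background_threshold(mat0)
  expect_equal(thr$neg_geomean, (5 * 1 * 4 * 9)^(1 / 4))
  expect_equal(thr$neg_sd, sd(c(5, 0, 4, 9)))
})

test_that("reference factors equalize reference geomeans (identity and 2x toys)", {
  # all samples identical -> all factors 1
  m <- matrix(rep(c(10L, 20L, 40L), 3), 3, 3)
  mat <- toy_panel(m, endo = 3, groups = c("case", "case", "control"))
  f <- reference_factors(mat, "top_n", n = 3)
  expect_equal(unname(f), rep(1, 3), ignore_attr = TRUE)

  # sample B = 2x sample A -> factors 1.5 and 0.75
  m2 <- cbind(A = c(10L, 20L, 40L), B = c(20L, 40L, 80L))
  mat2 <- toy_panel(m2, endo = 3)
  f2 <- reference_factors(mat2, "top_n", n = 3)
  expect_equal(unname(f2), c(1.5, 0.75), ignore_attr = TRUE)
  norm <- apply_normalization(mat2, f2, 0)
  ref <- attr(f2, "reference_probes")
  g <- apply(norm$values[ref, ], 2, geomean)
  expect_equal(unname(g[1]), unname(g[2]), tolerance = 1e-12)
})

test_that("spike-in reference uses exactly the panel's spike-in probes", {
  sim <- simulate_counts(simulation_config(fraction_profile = "ev_fraction",
                                           seed = 81))
  f <- reference_factors(sim$matrix, "spikein")
  expect_equal(length(attr(f, "reference_probes")), 6)
  expect_setequal(attr(f, "reference_probes"),
                  probes_of_class(sim$matrix, "SpikeIn"))
  expect_true(all(f > 0))
})

test_that("after normalization, per-sample reference geomeans agree to 1e-9", {
  for (ref in c("top_n", "spikein")) {
    sim <- simulate_counts(simulation_config(seed = 91, sample_scale_sd = 0.3))
    f <- reference_factors(sim$matrix, ref)
    norm <- apply_normalization(sim$matrix, f,
                                background_threshold(sim$matrix))
    g <- apply(norm$values[attr(f, "reference_probes"), ], 2, geomean)
    expect_lt(diff(range(g)) / mean(g), 1e-9)
  }
})

test_that("scaling one sample by c multiplies its factor by 1/c", {
  # use the full endogenous set as reference so scaling one sample cannot
  # reshuffle the reference membership
  sim <- simulate_counts(simulation_config(n_endogenous = 120, seed = 101))
  mat <- sim$matrix
  f <- reference_factors(mat, "top_n", n = 120)
  scaled <- mat$counts
  scaled[, 1] <- scaled[, 1] * 3L
  mat2 <- count_matrix(scaled, mat$probes, mat$samples)
  f2 <- reference_factors(mat2, "top_n", n = 120)
  expect_setequal(attr(f, "reference_probes"), attr(f2, "reference_probes"))
  # the scaled sample's geomean triples; every factor shares the new overall
  # mean, so compare the ratio against an unscaled sample
  expect_equal((f2[1] / f2[2]) / (f[1] / f[2]), 1 / 3, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("censoring flags raw counts strictly below the threshold", {
  mat <- toy_panel(matrix(c(5L, 10L, 15L, 20L), 2, byrow = TRUE), endo = 2)
  f <- stats::setNames(c(1, 1), mat$samples$sample_id)
  norm <- apply_normalization(mat, f, 10)
  expect_identical(unname(norm$detected),
                   matrix(c(FALSE, TRUE, TRUE, TRUE), 2, byrow = TRUE))
  # values equal raw counts under unit factors, nothing lost
  expect_equal(unname(norm$values), unname(mat$counts + 0))
  # algebraic inverse: dividing by factors recovers the raw counts exactly
  sim <- simulate_counts(simulation_config(n_endogenous = 30, seed = 111))
  f2 <- reference_factors(sim$matrix, "top_n", n = 10)
  norm2 <- apply_normalization(sim$matrix, f2, 0)
  back <- sweep(norm2$values, 2, f2[colnames(norm2$values)], `/`)
  expect_equal(back, sim$matrix$counts + 0, tolerance = 1e-12)

  expect_error(apply_normalization(mat, c(S01 = 1), 10), "missing")
})
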