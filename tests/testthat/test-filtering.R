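test_that("RIN gate keeps strictly-above-threshold cellular samples only", {
  sheet <- data.frame(
    sample_id = sprintf("S%02d", 1:30),
    fraction = "cell_fraction",
    rin = c(rep(8.5, 14), 6.9, 7.0, rep(9.1, 14))
  )
  res <- filter_by_rin(sheet)
  expect_equal(length(res$kept), 28)           # two failures, incl. RIN = 7.0
  expect_setequal(res$log$removed_ids, c("S15", "S16"))

  # EV samples are exempt even without RIN values
  ev <- data.frame(sample_id = c("E1", "E2"), fraction = "ev_fraction",
                   rin = NA_real_)
  expect_equal(filter_by_rin(ev)$kept, c("E1", "E2"))

  # missing RIN on a cellular sample is an integrity error
  bad <- data.frame(sample_id = "C1", fraction = "cell_fraction",
                    rin = NA_real_)
  expect_error(filter_by_rin(bad), "missing RIN")
})

test_that("low-coverage sample removal is boundary-inclusive at 40%", {
  det <- matrix(TRUE, 10, 3, dimnames = list(sprintf("p%02d", 1:10),
                                             c("ok", "s30", "s40")))
  det[1:3, "s30"] <- FALSE  # 30% below -> kept
  det[1:4, "s40"] <- FALSE  # 40% below -> removed (boundary inclusive)
  mask <- structure(list(detected = det, threshold = 10),
                    class = "detection_mask")
  res <- drop_low_coverage_samples(mask)
  expect_setequal(res$kept, c("ok", "s30"))
  expect_equal(res$log$removed_ids, "s40")

  all_ok <- structure(list(detected = matrix(TRUE, 5, 4,
                                             dimnames = list(letters[1:5],
                                                             LETTERS[1:4])),
                           threshold = 1), class = "detection_mask")
  expect_equal(length(drop_low_coverage_samples(all_ok)$kept), 4)
})

test_that("robust probe filter applies the either-group 75% rule inclusively", {
  # 12 controls, 4 cases; probe detected in 9/12 controls (exactly 0.75)
  det <- matrix(FALSE, 2, 16,
                dimnames = list(c("boundary", "weak"), sprintf("s%02d", 1:16)))
  groups <- setNames(rep(c("case", "control"), c(4, 12)), colnames(det))
  det["boundary", 5:13] <- TRUE                 # 9 of 12 controls, 0 cases
  det["weak", c(1:2, 5:12)] <- TRUE             # 50% cases, 8/12 controls
  mask <- structure(list(detected = det, threshold = 1),
                    class = "detection_mask")
  res <- robust_probe_filter(mask, groups)
  expect_equal(res$kept, "boundary")

  # brute-force oracle over random masks
  set.seed(1)
  for (rep_i in 1:20) {
    d <- matrix(runif(20 * 10) < 0.6, 20, 10,
                dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:10)))
    g <- setNames(rep(c("case", "control"), 5), colnames(d))
    m <- structure(list(detected = d, threshold = 1), class = "detection_mask")
    got <- robust_probe_filter(m, g)$kept
    want <- rownames(d)[vapply(rownames(d), function(p) {
      mean(d[p, g == "case"]) >= 0.75 || mean(d[p, g == "control"]) >= 0.75
    }, TRUE)]
    expect_identical(got, want)
  }

  one_group <- setNames(rep("case", 10), colnames(det)[1:10])
  m2 <- structure(list(detected = det[, 1:10], threshold = 1),
                  class = "detection_mask")
  expect_error(robust_probe_filter(m2, one_group), "no samples")
})

test_that("filters are stable under row/column permutation of the mask", {
  set.seed(2)
  d <- matrix(runif(15 * 8) < 0.55, 15, 8,
              dimnames = list(sprintf("p%02d", 1:15), sprintf("s%02d", 1:8)))
  g <- setNames(rep(c("case", "control"), 4), colnames(d))
  m <- structure(list(detected = d, threshold = 1), class = "detection_mask")
  mp <- structure(list(detected = d[sample(15), sample(8)], threshold = 1),
                  class = "detection_mask")
  expect_setequal(drop_low_coverage_samples(m)$kept,
                  drop_low_coverage_samples(mp)$kept)
  expect_setequal(robust_probe_filter(m, g)$kept,
                  robust_probe_filter(mp, g)$kept)
})

test_that("2-SD band removal matches its hand-computed cases", {
  # constant input: SD 0, nothing removed
  expect_equal(chauvenet_filter(c(5, 5, 5, 5))$removed, integer(0))
  # fewer than 3 values: no removal performed
  expect_equal(chauvenet_filter(c(0, 100))$removed, integer(0))
  # {0 x 9, 10}: mean 1, sample SD sqrt(10), band +/- 2 sqrt(10) ~ 6.32
  res <- chauvenet_filter(c(rep(0, 9), 10))
  expect_equal(res$removed, 10L)
  expect_equal(res$kept, rep(0, 9))
})

test_that("2-SD band removal equals the brute-force oracle on random lists", {
  set.seed(3)
  for (i in 1:300) {
    n <- sample(3:25, 1)
    v <- switch(sample(3, 1),
                rnorm(n, 100, 20),
                rnbinom(n, mu = 50, size = 2) + 0,
                c(rnorm(n - 1, 10, 1), 1000))
    expect_identical(chauvenet_filter(v)$removed, chauvenet_brute(v))
  }
})

test_that("removal set is order-invariant and the retention floor binds", {
  v <- c(rnorm(12, 50, 5), 500, -400)
  set.seed(4)
  perm <- sample(length(v))
  a <- chauvenet_filter(v)
  b <- chauvenet_filter(v[perm])
  expect_setequal(v[a$removed], v[perm][b$removed])

  # floor: with min_keep = n - 1 only the most extreme value may go
  v2 <- c(rep(0, 8), 50, 80)
  unrestricted <- chauvenet_filter(v2)
  floored <- chauvenet_filter(v2, min_keep = 9)
  expect_gt(length(unrestricted$removed) + length(floored$removed), 1)
  expect_equal(floored$removed, 10L)  # 80 is the most extreme
  expect_equal(chauvenet_filter(v2, min_keep = 10)$removed, integer(0))
})
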