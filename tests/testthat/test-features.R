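test_that("worked examples: median-centered moments", {
  expect_equal(median_center(c(1, 2, 3, 4, 5)), 3)
  expect_equal(median_center(c(1, 2, 3, 4)), 2.5)

  expect_equal(median_variance(c(1, 2, 3, 4, 5)), 2)
  expect_equal(median_variance(c(7, 7, 7)), 0)
  expect_equal(median_variance(c(1, 2, 3, 4, 10)), 11)

  expect_equal(median_std(c(1, 2, 3, 4, 5)), sqrt(2))
  expect_equal(median_std(c(7, 7, 7)), 0)

  expect_equal(median_skewness(c(1, 2, 3, 4, 5)), 0)
  expect_equal(median_skewness(c(1, 2, 3, 4, 10)), 67 / 11^1.5)
  # as-printed convention omits the 1/N factor
  expect_equal(median_skewness(c(1, 2, 3, 4, 10), raw = TRUE),
               5 * 67 / 11^1.5)

  expect_equal(median_kurtosis(c(-1, 1)), 1)
  expect_equal(median_kurtosis(c(-1, 1), raw = TRUE), 2)
})

test_that("worked examples: classical moments share the 1/N convention", {
  m <- classical_moments(c(1, 2, 3, 4, 5))
  expect_equal(unname(m), c(3, 2, 0, 1.7))
  expect_equal(unname(classical_moments(c(1, 2, 3, 4, 10))["variance"]), 10)
})

test_that("median kurtosis of a large normal sample is ~3", {
  x <- withr::with_seed(42, rnorm(1e5))
  expect_equal(median_kurtosis(x), 3, tolerance = 0.1 / 3)
  expect_equal(unname(classical_moments(x)["kurtosis"]), 3,
               tolerance = 0.1 / 3)
})

test_that("degenerate inputs error cleanly", {
  expect_error(median_center(numeric(0)), "non-empty")
  expect_error(median_variance(numeric(0)), "non-empty")
  expect_error(median_skewness(rep(2, 5)), "zero dispersion")
  expect_error(median_kurtosis(rep(0, 3)), "zero dispersion")
  expect_error(classical_moments(rep(1, 4)), "zero dispersion")
})

test_that("scalar ops agree with the brute-force oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:128, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                rexp(n),
                rt(n, df = 3) * 10)
    for (raw in c(FALSE, TRUE)) {
      o <- oracle_moments(x, "median", raw = raw)
      expect_equal(median_center(x), o$center, tolerance = 1e-12)
      expect_equal(median_variance(x), o$variance, tolerance = 1e-12)
      expect_equal(median_std(x), o$std, tolerance = 1e-12)
      expect_equal(median_skewness(x, raw = raw), o$skewness,
                   tolerance = 1e-9)
      expect_equal(median_kurtosis(x, raw = raw), o$kurtosis,
                   tolerance = 1e-9)
      oc <- oracle_moments(x, "mean", raw = raw)
      m <- classical_moments(x, raw = raw)
      expect_equal(unname(m["variance"]), oc$variance, tolerance = 1e-12)
      expect_equal(unname(m["skewness"]), oc$skewness, tolerance = 1e-9)
      expect_equal(unname(m["kurtosis"]), oc$kurtosis, tolerance = 1e-9)
    }
  }
})

test_that("moment properties: scale equivariance, sign flip, permutation", {
  x <- withr::with_seed(11, rexp(41))
  expect_equal(median_std(-2.5 * x), 2.5 * median_std(x))
  expect_equal(median_skewness(-x), -median_skewness(x))
  expect_equal(median_kurtosis(3 * x - 7), median_kurtosis(x))
  xs <- withr::with_seed(12, sample(x))
  expect_equal(median_center(xs), median_center(x))
  expect_equal(median_variance(xs), median_variance(x))
})

test_that("extract_features equals element-wise scalar ops per row", {
  set.seed(21)
  m <- matrix(rt(100 * 64, df = 4), nrow = 100)
  cs <- structure(list(cycles = m, L = 64L, r_offset = 26L, fs = 64,
                       subject_id = "s1", label = "healthy",
                       source_peaks = seq_len(100) * 70L),
                  class = "cycle_set", dropped = 0L)
  for (ck in c("median", "mean")) {
    ft <- extract_features(cs, ck)
    expect_equal(nrow(ft), 100)
    for (i in c(1, 17, 100)) {
      o <- oracle_moments(m[i, ], ck)
      expect_equal(ft$center[i], o$center, tolerance = 1e-9)
      expect_equal(ft$variance[i], o$variance, tolerance = 1e-9)
      expect_equal(ft$skewness[i], o$skewness, tolerance = 1e-9)
      expect_equal(ft$kurtosis[i], o$kurtosis, tolerance = 1e-9)
    }
  }
})

test_that("extract_features: symmetric rows give zero skewness and mean==median", {
  row <- c(-2, -1, 0, 1, 2)
  m <- matrix(rep(row, each = 6), nrow = 6)
  cs <- structure(list(cycles = m, L = 5L, r_offset = 2L, fs = 5,
                       subject_id = "s", label = "healthy",
                       source_peaks = seq_len(6) * 10L),
                  class = "cycle_set", dropped = 0L)
  fmed <- extract_features(cs, "median")
  fmean <- extract_features(cs, "mean")
  expect_equal(fmed$skewness, rep(0, 6))
  expect_equal(fmed[c("center", "variance", "skewness", "kurtosis")],
               fmean[c("center", "variance", "skewness", "kurtosis")])
})

test_that("zero-dispersion cycles are excluded with a count, not a crash", {
  m <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(0, 1, 0, 1))
  cs <- structure(list(cycles = m, L = 4L, r_offset = 1L, fs = 4,
                       subject_id = "s", label = "epilepsy",
                       source_peaks = c(10L, 20L, 30L)),
                  class = "cycle_set", dropped = 0L)
  expect_message(ft <- extract_features(cs, "median"), "zero-dispersion")
  expect_equal(nrow(ft), 2)
  expect_equal(attr(ft, "n_excluded"), 1L)
  expect_equal(ft$cycle, c(1L, 3L))
})
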