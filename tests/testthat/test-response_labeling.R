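test_that("spike counts bin correctly with trailing partial bins dropped", {
  b <- bin_counts(c(10, 12, 40, 41, 42), c(0, 90), 30)
  expect_equal(b$counts, c(2L, 3L, 0L))
  expect_equal(bin_counts(numeric(0), c(0, 300), 30)$counts, rep(0L, 10))
  # 300 s baseline at 30 s bins gives ten bins
  expect_length(bin_counts(runif(50, 0, 300), c(0, 300), 30)$counts, 10)
  # partial trailing bin is dropped, not rescaled
  b2 <- bin_counts(c(5, 65, 95), c(0, 100), 30)
  expect_equal(b2$counts, c(1L, 0L, 1L))
  expect_error(bin_counts(1, c(0, 20), 30), "shorter than one bin")
})

test_that("the most-active bin is selected with earliest-bin tie-breaking", {
  b <- bin_counts(c(10, 12, 40, 41, 42), c(0, 90), 30)
  m <- max_bin_mfr(b)
  expect_equal(m$mfr_hz, 0.1)
  expect_equal(m$bin, 2L)
  z <- max_bin_mfr(bin_counts(numeric(0), c(0, 60), 30))
  expect_equal(z$mfr_hz, 0)
  expect_equal(z$bin, 1L)
  tie <- max_bin_mfr(bin_counts(c(1, 2, 3, 4, 5, 31, 32, 33, 34, 35),
                                c(0, 60), 30))
  expect_equal(tie$mfr_hz, 5 / 30)
  expect_equal(tie$bin, 1L)
})

test_that("response deltas subtract baseline from treatment max-bin MFR", {
  # 5-spike baseline max bin, 10-spike treatment max bin
  ts <- c(seq(10, 14), seq(310, 319))
  d <- response_delta(ts, c(0, 300), c(300, 600), 30)
  expect_equal(d$delta_mfr_hz, 5 / 30)
  # stationary: identical max counts either side
  ts2 <- c(seq(10, 14), seq(310, 314))
  expect_equal(response_delta(ts2, c(0, 300), c(300, 600))$delta_mfr_hz, 0)
  # silenced unit: sign is preserved
  ts3 <- seq(100, 105) # 6 spikes, silent post-treatment
  expect_equal(response_delta(ts3, c(0, 300), c(300, 600))$delta_mfr_hz,
               -0.2)
})

test_that("Silverman bandwidth follows the robust rule exactly", {
  set.seed(42)
  x <- rnorm(100)
  expected <- 0.9 * min(sd(x), (quantile(x, 0.75) - quantile(x, 0.25)) /
                          1.349) * 100^(-1 / 5)
  expect_equal(silverman_bandwidth(x), unname(expected), tolerance = 1e-12)
  # scale equivariance
  expect_equal(silverman_bandwidth(3.7 * x), 3.7 * silverman_bandwidth(x),
               tolerance = 1e-12)
  expect_error(silverman_bandwidth(c(0, 0, 0)), "zero sample spread")
  expect_error(silverman_bandwidth(1), "at least 2")
})

test_that("the kernel density estimator matches the direct-sum oracle", {
  # single reference point: kernel value at zero
  m1 <- fit_kde(2.5, bandwidth = 0.3)
  expect_equal(kde_density(2.5, m1), 1 / (0.3 * sqrt(2 * pi)),
               tolerance = 1e-12)
  # 5-point reference set against the naive summation
  ref <- c(-1.2, 0.1, 0.4, 2.2, 5.0)
  m <- fit_kde(ref)
  xs <- seq(-3, 7, length.out = 41)
  expect_equal(kde_density(xs, m), kde_oracle(xs, ref, m$h),
               tolerance = 1e-12)
  # far in the Gaussian tail the density vanishes
  far <- max(ref) + 20 * m$h
  expect_lt(kde_density(far, m), 1e-20)
})

test_that("fitted densities are non-negative and integrate to one", {
  set.seed(7)
  for (ref in list(rnorm(50), rexp(200), runif(25, -4, 4))) {
    m <- fit_kde(ref)
    grid <- seq(min(ref) - 10 * m$h, max(ref) + 10 * m$h,
                length.out = 4000)
    dens <- kde_density(grid, m)
    expect_true(all(dens >= 0))
    integral <- sum(dens) * diff(grid[1:2])
    expect_gt(integral, 0.999)
    expect_lt(integral, 1.001)
  }
})

test_that("kernel density agrees with stats::density on a shared grid", {
  set.seed(11)
  ref <- rnorm(120)
  m <- fit_kde(ref)
  d <- stats::density(ref, bw = m$h, kernel = "gaussian", n = 512,
                      from = -3, to = 3)
  expect_equal(kde_density(d$x, m), d$y, tolerance = 1e-3)
})

test_that("self-application labels the percentile-threshold fraction", {
  set.seed(123)
  null_deltas <- rnorm(621, 0, 0.4)
  lab <- label_units(null_deltas, null_deltas, percentile_threshold = 10,
                     require_positive_delta = FALSE)
  expect_equal(mean(lab$label == "nociceptor"), 0.10, tolerance = 0.02)
  # treated drawn from the same distribution: same calibration
  treated <- rnorm(2000, 0, 0.4)
  lab2 <- label_units(treated, null_deltas,
                      require_positive_delta = FALSE)
  frac <- mean(lab2$label == "nociceptor")
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.12)
})

test_that("a far-tail treated unit is labeled nociceptor", {
  set.seed(5)
  null_deltas <- rnorm(400, 0, 0.3)
  m <- fit_kde(null_deltas)
  x_tail <- max(null_deltas) + 20 * m$h
  lab <- label_units(c(0, x_tail), null_deltas)
  expect_equal(lab$label, c("non-nociceptor", "nociceptor"))
  expect_lt(lab$kde_density[2], attr(lab, "density_threshold"))
})

test_that("the positivity flag separates silenced units from responders", {
  set.seed(9)
  null_deltas <- rnorm(500, 0, 0.3)
  silenced <- min(null_deltas) - 5
  driven <- max(null_deltas) + 5
  two_sided <- label_units(c(silenced, driven), null_deltas,
                           require_positive_delta = FALSE)
  expect_equal(two_sided$label, c("nociceptor", "nociceptor"))
  one_sided <- label_units(c(silenced, driven), null_deltas,
                           require_positive_delta = TRUE)
  expect_equal(one_sided$label, c("non-nociceptor", "nociceptor"))
})

test_that("raising the percentile threshold never shrinks the labeled set", {
  set.seed(33)
  null_deltas <- rnorm(400, 0, 0.5)
  treated <- rnorm(300, 0.3, 0.8)
  counts <- vapply(c(5, 10, 20, 40, 60), function(p) {
    sum(label_units(treated, null_deltas, percentile_threshold = p,
                    require_positive_delta = FALSE)$label == "nociceptor")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("degenerate labeling inputs fail loudly", {
  expect_error(label_units(numeric(0), rnorm(10)), "empty treated")
  expect_error(label_units(rnorm(5), rep(1, 10)), "zero sample spread")
  expect_error(label_units(rnorm(5), rnorm(10), percentile_threshold = 0),
               "percentile_threshold")
})
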