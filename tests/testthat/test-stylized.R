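test_that("velocity returns are first differences of angular velocity", {
  expect_equal(velocity_returns(fake_trajectory(c(0, 1, 3)))$values,
               c(1, 2))
  expect_equal(velocity_returns(fake_trajectory(rep(2, 50)))$values,
               rep(0, 49))
  expect_error(velocity_returns(fake_trajectory(0.5)), "at least 2")
})

test_that("pooled normalization z-scores the pooled sample", {
  s <- returns_series(c(0, 1, 2, 3), source = "synthetic")
  pooled <- normalize_and_pool(list(s))
  expect_equal(mean(pooled$values), 0, tolerance = 1e-12)
  expect_equal(sd(pooled$values), 1, tolerance = 1e-12)
  expect_true(pooled$normalized)
  expect_equal(pooled$norm_mean, 1.5)
})

test_that("pooling duplicated series leaves the normalized values alike", {
  s <- returns_series(rnorm(500), source = "synthetic")
  one <- normalize_and_pool(list(s))
  two <- normalize_and_pool(list(s, s))
  # identical up to the n-1 vs 2n-1 variance denominators, an O(1/n) effect
  expect_lt(max(abs(two$values - rep(one$values, 2))), 0.01)
})

test_that("renormalizing an already-normalized singleton is a no-op", {
  s <- returns_series(rnorm(1000), source = "simulated")
  once <- normalize_and_pool(list(s))
  twice <- normalize_and_pool(list(once))
  expect_lt(max(abs(twice$values - once$values)), 1e-9)
})

test_that("zero-variance series are rejected by name", {
  good <- returns_series(rnorm(100), source = "synthetic")
  flat <- returns_series(rep(1, 100), source = "synthetic")
  expect_error(normalize_and_pool(list(good, flat)), "series 2")
})

test_that("empirical PDF of a standard normal peaks at the normal density", {
  set.seed(101)
  s <- returns_series(rnorm(1e6), source = "synthetic")
  pdf <- empirical_pdf(s, n_bins = 61, span_sds = 5)
  center <- (61 + 1) / 2
  expect_equal(pdf$density[center], dnorm(0), tolerance = 0.02)
  expect_lt(pdf$out_of_range, 1e-5)
})

test_that("empirical PDF of uniform data is flat at the analytic density", {
  set.seed(102)
  s <- returns_series(runif(1e5, -1, 1), source = "synthetic")
  pdf <- empirical_pdf(s, n_bins = 41, span_sds = 1)
  expect_true(all(abs(pdf$density - 0.5) < 0.05))
})

test_that("PDF mass equals one minus the out-of-range fraction", {
  for (seed in 1:3) {
    set.seed(seed)
    s <- returns_series(rt(5000, df = 2), source = "synthetic")
    pdf <- empirical_pdf(s, n_bins = 21, span_sds = 3)
    expect_equal(sum(pdf$density) * pdf$bin_width + pdf$out_of_range, 1,
                 tolerance = 1e-12)
  }
})

test_that("degenerate and undersized inputs to empirical_pdf error", {
  expect_error(empirical_pdf(returns_series(rep(1, 200),
                                            source = "synthetic")),
               "variance")
  expect_error(empirical_pdf(returns_series(rnorm(50),
                                            source = "synthetic")),
               "at least 100")
  expect_error(empirical_pdf(returns_series(rnorm(200),
                                            source = "synthetic"),
                             n_bins = 60),
               "odd")
})

test_that("ACF at lag zero is one and AR(1) decays geometrically", {
  set.seed(7)
  x <- as.numeric(arima.sim(list(ar = 0.6), n = 1e5))
  a <- acf_returns(returns_series(x, source = "synthetic"), max_lag = 10)
  expect_equal(a$rho[1], 1)
  expect_true(all(abs(a$rho[-1] - 0.6^(1:10)) < 0.02))
})

test_that("degenerate transforms for the ACF are detected", {
  pm1 <- returns_series(rep(c(1, -1), 50), source = "synthetic")
  expect_error(acf_returns(pm1, max_lag = 5, absolute = TRUE),
               "absolute")
  expect_error(acf_returns(returns_series(rnorm(50), source = "synthetic"),
                           max_lag = 50),
               "exceed")
})

test_that("heteroskedasticity-robust band reduces to 3/sqrt(n) for iid data", {
  set.seed(11)
  x <- rnorm(5e4)
  band <- robust_acf_band(x, 20)
  expect_true(all(abs(band - 3 / sqrt(5e4)) < 0.2 * 3 / sqrt(5e4)))
})

test_that("calibrated pooled returns carry the intermittency signature", {
  pooled <- calibrated_pooled(31)
  expect_gt(excess_kurtosis(pooled), 3)
  ab <- acf_returns(pooled, max_lag = 10, absolute = TRUE)
  expect_true(all(ab$rho[-1] > 0))       # volatility clustering
  raw <- acf_returns(pooled, max_lag = 100, absolute = FALSE)
  band <- robust_acf_band(pooled$values, 100)
  expect_gte(mean(abs(raw$rho[-1]) <= band), 0.9)
})

test_that("PDF and ACF export to two-column CSVs", {
  pooled <- calibrated_pooled(31)
  dir <- withr::local_tempdir()
  write_pdf_csv(empirical_pdf(pooled), file.path(dir, "pdf.csv"))
  write_acf_csv(acf_returns(pooled, 20), file.path(dir, "acf.csv"))
  pdf_df <- read.csv(file.path(dir, "pdf.csv"))
  acf_df <- read.csv(file.path(dir, "acf.csv"))
  expect_equal(names(pdf_df), c("x", "density"))
  expect_equal(names(acf_df), c("lag", "rho"))
  expect_equal(nrow(acf_df), 21)
})
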