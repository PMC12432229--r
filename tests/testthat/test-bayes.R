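test_that("BEST: null samples give BF10 < 1 and an HDI covering zero", {
  set.seed(21)
  a <- rnorm(100); b <- rnorm(100)
  r <- best_bayes_compare(a, b, seed = 5)
  expect_lt(r$bayes_factor_10, 1)
  expect_lte(r$hdi_low, 0)
  expect_gte(r$hdi_high, 0)
  expect_true(is.na(r$p_value))
  expect_true(r$details$converged %in% c(TRUE, NA))
})

test_that("BEST: five-SD-separated samples give BF10 > 100 and an HDI excluding zero", {
  set.seed(22)
  a <- rnorm(100); b <- rnorm(100) + 5
  r <- best_bayes_compare(a, b, seed = 6)
  expect_gt(r$bayes_factor_10, 100)
  expect_gt(r$details$jzs_bf10, 100)       # analytic cross-check agrees in kind
  expect_true(r$hdi_high < 0 || r$hdi_low > 0)
  # swapping the groups negates the posterior mean difference (within MC error)
  r2 <- best_bayes_compare(b, a, seed = 6)
  expect_equal(r2$statistic, -r$statistic, tolerance = 0.05)
})

test_that("JZS factor is sensible at known anchor points", {
  # t = 0 is evidence for the null under the default prior
  expect_lt(jzs_bf_two_sample(0, 50, 50), 1)
  # monotone in |t|
  bfs <- vapply(c(1, 2, 4, 8), function(t) jzs_bf_two_sample(t, 50, 50), 0)
  expect_true(all(diff(bfs) > 0))
})

test_that("Bayesian rank correlation: null shrinks BF, monotone pairs explode it", {
  set.seed(23)
  r0 <- bayes_correlation(rnorm(200), rnorm(200))
  expect_lt(r0$bayes_factor_10, 1)
  expect_lte(r0$hdi_low, r0$hdi_high)
  r1 <- bayes_correlation(1:50, exp(1:50 / 10))
  expect_gt(r1$bayes_factor_10, 100)
  expect_gt(r1$hdi_low, 0.9)
  # HDI bounds are always ordered
  for (k in 1:5) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    rr <- bayes_correlation(x, y)
    expect_lte(rr$hdi_low, rr$hdi_high)
  }
  expect_error(bayes_correlation(1:3, 1:4), "length")
})

test_that("sample HDI is the narrowest interval with the requested mass", {
  set.seed(24)
  x <- c(rnorm(5000), rnorm(100, 10))      # mass concentrated near 0
  h <- hdi_of_sample(x, 0.9)
  expect_lt(h[2] - h[1], quantile(x, 0.95) - quantile(x, 0.05))
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.9 - 0.01)
})
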