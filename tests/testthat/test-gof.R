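test_that("information criteria follow their defining arithmetic", {
  # l = -100, k = 3, n = 100
  x <- rtihtw(100, 1.4, 1, 0.9, seed = 6)
  fit <- fit_mle(x, "tihtw")
  dm <- discrimination_measures(fit)
  expect_equal(dm$aic, -2 * fit$loglik + 6)
  expect_equal(dm$bic, dm$aic - 6 + 3 * log(100))
  expect_equal(-2 * -100 + 2 * 3, 206)
  expect_equal(206 - 6 + 3 * log(100), 213.8155, tolerance = 1e-4)
})

test_that("EDF statistics reproduce their plug-in values and a direct loop", {
  n <- 20
  u <- (seq_len(n) - 0.5) / n
  # data placed exactly at the fitted quantiles zeroes the CM sum
  x <- qtihtw(u, 1.4, 1, 0.9)
  s <- edf_statistics(x, function(q) ptihtw(q, 1.4, 1, 0.9))
  expect_equal(s$cm, 1 / (12 * n), tolerance = 1e-10)
  # AD against an independent elementwise loop
  ad_loop <- 0
  for (i in seq_len(n)) {
    ad_loop <- ad_loop + (2 * i - 1) * (log(u[i]) + log(1 - u[n + 1 - i]))
  }
  expect_equal(s$ad, -n - ad_loop / n, tolerance = 1e-10)
  # KS against the stats oracle on random data
  set.seed(14)
  y <- rexp(50, 0.3)
  s2 <- edf_statistics(y, function(q) pexp(q, 0.3))
  ks_ref <- suppressWarnings(ks.test(y, pexp, 0.3, exact = FALSE))
  expect_equal(s2$ks, unname(ks_ref$statistic), tolerance = 1e-10)
  expect_equal(s2$ks_pvalue, ks_ref$p.value, tolerance = 1e-3)
})

test_that("the KS p-value is calibrated under the null", {
  set.seed(5)
  y <- runif(1e4)
  s <- edf_statistics(y, identity)
  expect_gt(s$ks_pvalue, 0.001)
})

test_that("EDF statistics survive the probability integral transform", {
  x <- rtihtw(80, 1.2, 1, 0.8, seed = 9)
  s1 <- edf_statistics(x, function(q) ptihtw(q, 1.2, 1, 0.8))
  # strictly increasing transform with matching cdf transform
  s2 <- edf_statistics(exp(x), function(q) ptihtw(log(q), 1.2, 1, 0.8))
  expect_equal(s1$cm, s2$cm, tolerance = 1e-12)
  expect_equal(s1$ad, s2$ad, tolerance = 1e-12)
  expect_equal(s1$ks, s2$ks, tolerance = 1e-12)
})

test_that("boundary cdf values are nudged with a warning, not fatal", {
  x <- c(1e-300, 1, 2, 3, 1e10)
  expect_warning(s <- edf_statistics(x, function(q) pexp(q, 1)), "interior")
  expect_true(is.finite(s$cm) && is.finite(s$ks))
})

test_that("model comparison ranks by AIC and keeps every family", {
  x <- rtihtw(400, 1.4, 0.03, 2, seed = 31)
  tab <- compare_models(x, c("tihtw", "weibull", "lomax", "burr12"))
  expect_setequal(tab$family, c("tihtw", "weibull", "lomax", "burr12"))
  ok <- tab[tab$converged, ]
  expect_true(all(diff(ok$aic) >= 0))
  # bic - aic = k (log n - 2) exactly, per row
  expect_equal(ok$bic - ok$aic, ok$k_params * (log(400) - 2), tolerance = 1e-10)
  expect_error(compare_models(x, "tihtw"), "two families")
})

test_that("TI-HTW wins its own data and concedes at most the penalty on Weibull data", {
  # a strongly heavy-tailed generating point (theta far below 1) makes the
  # extra parameter earn its AIC penalty in nearly every repetition
  wins <- 0L
  for (seed in 1:50) {
    x <- rtihtw(800, 1.4, 0.03, 0.2, seed = 1000 + seed)
    f1 <- fit_mle(x, "tihtw", se = FALSE)
    f0 <- fit_mle(x, "weibull", se = FALSE)
    if (f1$aic < f0$aic) wins <- wins + 1L
  }
  expect_gte(wins, 45L) # >= 90% of 50 repetitions
  # nested-null behaviour: on Weibull data the AIC gap is about the penalty
  gaps <- vapply(1:10, function(seed) {
    x <- rtihtw(400, 1.1, 0.5, 1, seed = 2000 + seed)
    fit_mle(x, "tihtw", se = FALSE)$aic - fit_mle(x, "weibull", se = FALSE)$aic
  }, numeric(1))
  expect_lte(median(gaps), 2.5)
  expect_gte(min(gaps), -4)
})
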