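test_that("theta = 1 collapses every evaluator to the baseline at machine precision", {
  b <- baseline_weibull(0.8, 1.3)
  x <- c(0.1, 0.5, 1, 2.5, 7)
  u <- c(0.01, 0.25, 0.5, 0.9, 0.999)
  expect_identical(ptiht(x, 1, b), b$cdf(x))
  expect_equal(dtiht(x, 1, b), b$pdf(x), tolerance = 1e-15)
  expect_identical(qtiht(u, 1, b), b$quantile(u))
  expect_equal(ptihtw(x, 0.8, 1.3, 1), pweibull(x, 0.8, 1.3^(-1 / 0.8)),
               tolerance = 1e-15)
  expect_equal(dtihtw(x, 0.8, 1.3, 1), dweibull(x, 0.8, 1.3^(-1 / 0.8)),
               tolerance = 1e-14)
})

test_that("cdf agrees with cumulative quadrature of the pdf and normalizes", {
  # adaptive-quadrature oracle on a grid
  for (x in c(0.5, 1, 2, 5)) {
    q <- integrate(function(t) dtihtw(t, 0.8, 1, 0.5), 0, x,
                   rel.tol = 1e-9)$value
    expect_equal(ptihtw(x, 0.8, 1, 0.5), q, tolerance = 1e-6)
  }
  expect_equal(integrate(function(t) dtihtw(t, 1.4, 1, 0.9), 0, Inf,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  # finite-difference oracle for the density
  h <- 1e-6
  fd <- (ptihtw(1.3 + h, 0.8, 0.5, 1) - ptihtw(1.3 - h, 0.8, 0.5, 1)) / (2 * h)
  expect_equal(dtihtw(1.3, 0.8, 0.5, 1), fd, tolerance = 1e-5)
  expect_identical(ptihtw(0, 1.4, 1, 0.9), 0)
  expect_identical(dtihtw(-1, 1.4, 1, 0.9), 0)
})

test_that("quantile inverts the cdf across the unit interval", {
  u <- c(1e-8, seq(0.05, 0.95, by = 0.05), 1 - 1e-6, 1 - 1e-12)
  for (par in list(c(0.8, 1, 0.5), c(1.4, 1, 0.9), c(1.2, 0.7, 1.6))) {
    x <- qtihtw(u, par[1], par[2], par[3])
    expect_equal(ptihtw(x, par[1], par[2], par[3]), u, tolerance = 1e-9)
  }
  expect_identical(qtihtw(0, 1.4, 1, 0.9), 0)
  # Rayleigh median closed form at the theta = 1 reduction
  expect_equal(qtihtw(0.5, 2, 1, 1), sqrt(log(2)), tolerance = 1e-12)
  # independent bracketing bisection oracle
  root <- uniroot(function(x) ptihtw(x, 1.2, 0.7, 0.9) - 0.95,
                  c(1e-8, 100), tol = 1e-12)$root
  expect_equal(qtihtw(0.95, 1.2, 0.7, 0.9), root, tolerance = 1e-8)
  expect_error(qtihtw(1, 1, 1, 0.5), "0, 1")
  expect_error(qtihtw(-0.1, 1, 1, 0.5), "0, 1")
})

test_that("survival is stable deep in the tail and satisfies the heavy-tail criterion", {
  expect_identical(stihtw(0, 1, 1, 0.9), 1)
  # strict heavy tail (alpha < 1): sf(x) e^(px) diverges for small p since
  # the stretched-exponential tail e^(-theta*gamma*x^alpha) beats every
  # exponential tilt eventually
  xg <- c(50, 100, 200, 400, 800)
  v <- stihtw(xg, 0.5, 1, 0.9, log.p = TRUE) + 0.1 * xg
  expect_true(all(diff(v) > 0))
  expect_gt(v[length(v)], 20)
  # alpha = 1: the tail rate drops from gamma to theta*gamma, so the
  # survival beats every exponential with rate between the two — in
  # particular the baseline's own tail
  v1 <- stihtw(xg, 1, 1, 0.9, log.p = TRUE) + 0.95 * xg
  expect_true(all(diff(v1) > 0))
  # sf / exp(-theta*gamma*x^alpha) -> theta^(-theta)
  xg <- 10^seq(0.5, 2, length.out = 8)
  ratio <- exp(stihtw(xg, 1.1, 0.8, 0.6, log.p = TRUE) + 0.6 * 0.8 * xg^1.1)
  expect_equal(ratio[length(ratio)], 0.6^(-0.6), tolerance = 0.01)
  # no 1 - cdf subtraction: survival keeps full relative accuracy far past
  # the point where the cdf rounds to 1 in doubles
  expect_gt(stihtw(30, 1.1, 0.8, 0.6), 0)
  expect_lt(stihtw(30, 1.1, 0.8, 0.6), 1e-8)
  expect_gt(stihtw(80, 1.1, 0.8, 0.6), 0)
  expect_lt(stihtw(80, 1.1, 0.8, 0.6), 1e-24)
  # hazard is pdf / sf wherever both are representable
  x <- c(0.3, 1.7, 4.2)
  expect_equal(htihtw(x, 1.4, 1, 0.9),
               dtihtw(x, 1.4, 1, 0.9) / stihtw(x, 1.4, 1, 0.9),
               tolerance = 1e-12)
  # at theta*gamma*x^alpha ~ 1e12 the log-route subtraction leaves ~1e-5
  # relative error; the value stays finite and correct to that accuracy
  expect_equal(htihtw(1e6, 2, 1, 1), 2e6, tolerance = 1e-4)
  expect_error(htihtw(1e160, 2, 1, 1), "underflow")
})

test_that("theta orders the tail against the Weibull baseline", {
  u <- seq(0.7, 0.999, by = 0.01)
  qw <- qtihtw(u, 1.2, 0.7, 1)
  expect_true(all(qtihtw(u, 1.2, 0.7, 0.6) > qw)) # heavier tail
  expect_true(all(qtihtw(u, 1.2, 0.7, 1.7) < qw)) # lighter tail
})

test_that("inversion sampling is seeded, positive and distributionally correct", {
  b <- baseline_weibull(0.8, 0.5)
  x1 <- rtiht(500, 1, b, seed = 42)
  x2 <- rtiht(500, 1, b, seed = 42)
  expect_identical(x1, x2)
  expect_true(all(x1 > 0))
  expect_error(rtiht(0, 1, b, seed = 1), ">= 1")
  expect_error(rtiht(10, 1, b), "seed")
  # one-sample KS bound at the 0.001 level
  n <- 1e5
  x <- rtihtw(n, 0.8, 0.5, 1, seed = 7)
  d <- suppressWarnings(
    ks.test(x, function(q) ptihtw(q, 0.8, 0.5, 1))$statistic
  )
  expect_lt(unname(d), 1.95 / sqrt(n))
})

test_that("invalid parameters and inputs are rejected", {
  b <- baseline_weibull(1, 1)
  expect_error(ptiht(1, -0.5, b), "positive")
  expect_error(ptiht(1, 0, b), "positive")
  expect_error(baseline_weibull(-1, 1), "positive")
  expect_error(ptiht(Inf, 0.5, b), "finite")
})
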