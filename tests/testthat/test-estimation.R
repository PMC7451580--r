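test_that("the log-likelihood matches its structural form and anchors", {
  # exponential density at x = 1: log f = -1
  expect_equal(log_likelihood(c(1, 1, 1), 1, "tihtw"), -1, tolerance = 1e-14)
  # dual-formula oracle: pdf-sum route vs the term-by-term structural form
  x <- rtihtw(50, 1.1, 0.8, 0.7, seed = 21)
  for (par in list(c(1.1, 0.8, 0.7), c(0.6, 1.3, 1.4), c(2, 0.4, 0.9))) {
    expect_equal(log_likelihood(par, x, "tihtw"),
                 tihtw_loglik_structural(par, x), tolerance = 1e-10)
  }
  # theta = 1 reduces to the Weibull log-likelihood
  expect_equal(log_likelihood(c(1.1, 0.8, 1), x, "tihtw"),
               sum(log(1.1 * 0.8 * x^0.1 * exp(-0.8 * x^1.1))),
               tolerance = 1e-10)
  # optimizer-safe domain handling, data validation
  expect_identical(log_likelihood(c(-1, 1, 1), x, "tihtw"), -Inf)
  expect_error(log_likelihood(c(1, 1, 1), c(x, -2), "tihtw"), "positive")
})

test_that("the analytic score matches central finite differences", {
  x <- rtihtw(30, 0.9, 1.2, 0.6, seed = 8)
  for (par in list(c(0.9, 1.2, 0.6), c(1.5, 0.5, 1.3), c(0.7, 2, 1))) {
    fd <- fd_gradient(function(p) log_likelihood(p, x, "tihtw"), par)
    expect_equal(unname(tihtw_score(par, x)), fd, tolerance = 1e-5)
  }
  # near-zero gradient at the fitted optimum
  fit <- fit_mle(x, "tihtw")
  expect_lt(max(abs(tihtw_score(fit$estimates, x))), 1e-4 * length(x))
})

test_that("maximum likelihood recovers generating parameters at large n", {
  x <- rtihtw(5000, 0.8, 1, 0.5, seed = 1)
  fit <- fit_mle(x, "tihtw")
  expect_true(fit$converged)
  truth <- c(alpha = 0.8, gamma = 1, theta = 0.5)
  expect_true(all(abs(fit$estimates - truth) < 3 * fit$std_errors))
  # refitting from the optimum is a fixed point
  refit <- fit_mle(x, "tihtw", init = fit$estimates)
  expect_equal(refit$estimates, fit$estimates, tolerance = 1e-6)
  # bookkeeping identities
  expect_equal(fit$loglik, log_likelihood(fit$estimates, x, "tihtw"))
  expect_equal(fit$aic, -2 * fit$loglik + 6)
  expect_equal(fit$bic, -2 * fit$loglik + 3 * log(5000))
  expect_true(all(fit$ci_lower < fit$estimates & fit$estimates < fit$ci_upper))
})

test_that("TI-HTW never fits worse than its nested Weibull", {
  for (seed in 1:4) {
    x <- rtihtw(300, 1.2, 0.6, if (seed %% 2) 0.7 else 1.8, seed = seed)
    f1 <- fit_mle(x, "tihtw", se = FALSE)
    f0 <- fit_mle(x, "weibull", se = FALSE)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
  }
})

test_that("estimates are equivariant under data rescaling", {
  x <- rtihtw(2000, 1.3, 0.9, 0.7, seed = 33)
  f1 <- fit_mle(x, "tihtw", se = FALSE)
  f2 <- fit_mle(x * 2.5, "tihtw", se = FALSE)
  expect_equal(f2$estimates[["alpha"]], f1$estimates[["alpha"]], tolerance = 1e-3)
  expect_equal(f2$estimates[["theta"]], f1$estimates[["theta"]], tolerance = 1e-3)
  expect_equal(f2$estimates[["gamma"]],
               f1$estimates[["gamma"]] / 2.5^f1$estimates[["alpha"]],
               tolerance = 1e-3)
})

test_that("Wald intervals carry the normal multiplier and shrink like 1/sqrt(n)", {
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
  x <- rtihtw(4000, 1.4, 1, 0.9, seed = 12)
  f_small <- fit_mle(x[1:500], "tihtw", init = c(1.4, 1, 0.9))
  f_large <- fit_mle(x, "tihtw", init = c(1.4, 1, 0.9))
  w_small <- f_small$ci_upper - f_small$ci_lower
  w_large <- f_large$ci_upper - f_large$ci_lower
  # nominal sqrt(4000/500) ~ 2.83, blurred by the ridge curvature differing
  # between the two optima; the scaling direction is what is asserted
  ratio <- w_small / w_large
  expect_true(all(ratio > 1.3 & ratio < 6))
  ci <- wald_ci(f_large, 0.9)
  expect_equal(ci$conf.high - ci$conf.low,
               2 * qnorm(0.95) * ci$std.error, tolerance = 1e-12)
  expect_error(wald_ci(f_large, 1.2), "0, 1")
  # untruncated intervals: small-n theta bound may go negative
  x2 <- rtihtw(40, 0.8, 1, 0.5, seed = 4)
  f2 <- fit_mle(x2, "tihtw")
  expect_true(is.numeric(f2$ci_lower)) # no clamping applied
})

test_that("broom methods expose the fit as tidy tables", {
  x <- rtihtw(300, 1.4, 1, 0.9, seed = 2)
  fit <- fit_mle(x, "tihtw")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(td$term, c("alpha", "gamma", "theta"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 300L)
  expect_equal(gl$AIC, fit$aic)
  expect_s3_class(autoplot(fit), "ggplot")
})
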