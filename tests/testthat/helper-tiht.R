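# shared fixtures: everything is generated in code, nothing read from disk

# central finite difference of a scalar function of a parameter vector
fd_gradient <- function(f, par, h_scale = 1e-6) {
  vapply(seq_along(par), function(j) {
    h <- h_scale * (1 + abs(par[j]))
    ep <- em <- par
    ep[j] <- par[j] + h
    em[j] <- par[j] - h
    (f(ep) - f(em)) / (2 * h)
  }, numeric(1))
}

# compare two independent equal-size Monte Carlo estimates: the reference
# value is itself a replicate mean with the same spread as ours, so the
# standard error of the difference carries a sqrt(2)
expect_mc_close <- function(estimate, reference, mc_se) {
  expect_lt(abs(estimate - reference), 3 * sqrt(2) * mc_se)
}

# the structural TI-HT log-likelihood written out term by term, used as the
# dual-formula oracle against the pdf-sum route
tihtw_loglik_structural <- function(par, x) {
  alpha <- par[1]; gamma <- par[2]; theta <- par[3]
  n <- length(x)
  f_b <- alpha * gamma * x^(alpha - 1) * exp(-gamma * x^alpha)
  F_b <- 1 - exp(-gamma * x^alpha)
  2 * n * log(theta) + sum(log(f_b)) + (theta - 1) * sum(log(1 - F_b)) -
    (theta + 1) * sum(log(1 - (1 - theta) * F_b))
}
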