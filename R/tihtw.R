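#' The type-I heavy-tailed Weibull (TI-HTW) distribution
#'
#' Closed-form evaluators for the three-parameter TI-HTW distribution, the
#' Weibull special case of the TI-HT transform:
#' \deqn{G(x) = 1 - \left\{\frac{e^{-\gamma x^\alpha}}
#'   {1-(1-\theta)(1-e^{-\gamma x^\alpha})}\right\}^\theta, \quad x > 0,}
#' \deqn{g(x) = \frac{\alpha\theta^2\gamma x^{\alpha-1} e^{-\theta\gamma
#'   x^\alpha}}{\{1-(1-\theta)(1-e^{-\gamma x^\alpha})\}^{\theta+1}}.}
#' `alpha` is the Weibull shape, `gamma` the Weibull *rate-type* parameter
#' (`F = 1 - exp(-gamma x^alpha)`), and `theta` the tail parameter; `theta = 1`
#' recovers Weibull(`alpha`, `gamma`) exactly, and `theta < 1` yields a
#' heavier-than-Weibull tail (the survival function then beats every
#' exponential, the defining heavy-tail property).
#'
#' These closed forms agree with the generic transform
#' `ptiht(x, theta, baseline_weibull(alpha, gamma))` to machine precision.
#'
#' @param x,q Vector of evaluation points.
#' @param p Vector of probabilities in `[0, 1)`.
#' @param n Number of draws.
#' @param alpha,gamma,theta Strictly positive parameters.
#' @param log,log.p,lower.tail As in the base distribution functions.
#' @param seed Integer seed for inversion sampling (required; the global RNG
#'   is untouched).
#'
#' @examples
#' ptihtw(2, alpha = 0.8, gamma = 1, theta = 0.5)
#' qtihtw(0.95, 1.2, 0.7, 0.9) # the 95% VaR
#' @name tihtw
NULL

check_tihtw <- function(alpha, gamma, theta) {
  check_pos(alpha, "alpha")
  check_pos(gamma, "gamma")
  check_pos(theta, "theta")
  invisible(NULL)
}

#' @rdname tihtw
#' @export
dtihtw <- function(x, alpha, gamma, theta, log = FALSE) {
  check_tihtw(alpha, gamma, theta)
  ld <- ifelse(x <= 0, -Inf,
    base::log(alpha) + 2 * base::log(theta) + base::log(gamma) +
      (alpha - 1) * base::log(x) - theta * gamma * x^alpha -
      (theta + 1) * base::log(tiht_denom(theta, exp(-gamma * x^alpha)))
  )
  if (log) ld else exp(ld)
}

#' @rdname tihtw
#' @export
ptihtw <- function(q, alpha, gamma, theta, lower.tail = TRUE, log.p = FALSE) {
  check_tihtw(alpha, gamma, theta)
  lsf <- ifelse(q <= 0, 0,
    theta * (-gamma * q^alpha -
      base::log(tiht_denom(theta, exp(-gamma * q^alpha))))
  )
  if (lower.tail) {
    out <- -expm1(lsf)
    if (log.p) log(out) else out
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname tihtw
#' @export
stihtw <- function(q, alpha, gamma, theta, log.p = FALSE) {
  ptihtw(q, alpha, gamma, theta, lower.tail = FALSE, log.p = log.p)
}

#' @rdname tihtw
#' @export
htihtw <- function(x, alpha, gamma, theta) {
  lsf <- stihtw(x, alpha, gamma, theta, log.p = TRUE)
  if (any(is.infinite(lsf) & lsf < 0 & x > 0)) {
    abort(paste(
      "survival underflows to 0 at some `x`; evaluate the hazard on the log",
      "scale via dtihtw(log=TRUE) - stihtw(log.p=TRUE)."
    ))
  }
  exp(dtihtw(x, alpha, gamma, theta, log = TRUE) - lsf)
}

#' @rdname tihtw
#' @export
qtihtw <- function(p, alpha, gamma, theta) {
  check_tihtw(alpha, gamma, theta)
  if (any(p < 0 | p >= 1, na.rm = TRUE)) abort("`p` must lie in [0, 1).")
  if (abs(theta - 1) < 1e-12) {
    return((-log1p(-p) / gamma)^(1 / alpha))
  }
  logt <- log1p(-p) / theta
  log_sfb <- base::log(theta) + logt - log1p(-(1 - theta) * exp(logt))
  out <- (-log_sfb / gamma)^(1 / alpha)
  out[p == 0] <- 0
  out
}

#' @rdname tihtw
#' @export
rtihtw <- function(n, alpha, gamma, theta, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("`n` must be >= 1.")
  if (missing(seed)) abort("`seed` is required: draws must be reproducible.")
  u <- withr::with_seed(as.integer(seed), runif(as.integer(n)))
  qtihtw(u, alpha, gamma, theta)
}

#' Named special cases of the TI-HTW distribution
#'
#' Maps a TI-HTW parameter triple to the sub-model it reduces to:
#' `theta = 1` gives Weibull(`alpha`, `gamma`) (one-parameter Weibull when
#' also `gamma = 1`, exponential when `alpha = 1`, Rayleigh when `alpha = 2`);
#' `alpha = 1` gives the type-I heavy-tailed exponential (TI-HTE) and
#' `alpha = 2` the type-I heavy-tailed Rayleigh (TI-HTR).
#'
#' @inheritParams tihtw
#' @param tol Equality tolerance for detecting the special values.
#' @return A list with the reduced `model` name and its `params`.
#' @examples
#' reduce_special_case(alpha = 2, gamma = 0.5, theta = 1) # Rayleigh
#' @export
reduce_special_case <- function(alpha, gamma, theta, tol = 1e-12) {
  check_tihtw(alpha, gamma, theta)
  eq <- function(a, b) abs(a - b) < tol
  if (eq(theta, 1)) {
    if (eq(alpha, 1)) {
      list(model = "exponential", params = c(gamma = gamma))
    } else if (eq(alpha, 2)) {
      list(model = "rayleigh", params = c(gamma = gamma))
    } else if (eq(gamma, 1)) {
      list(model = "weibull1", params = c(alpha = alpha))
    } else {
      list(model = "weibull", params = c(alpha = alpha, gamma = gamma))
    }
  } else if (eq(alpha, 1)) {
    list(model = "tihte", params = c(theta = theta, gamma = gamma))
  } else if (eq(alpha, 2)) {
    list(model = "tihtr", params = c(theta = theta, gamma = gamma))
  } else {
    list(model = "tihtw", params = c(alpha = alpha, gamma = gamma, theta = theta))
  }
}
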