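#' Baseline lifetime distributions for the TI-HT transform
#'
#' The TI-HT family is built by transforming a baseline lifetime distribution
#' `F(x; xi)` with support on the positive half-line. A baseline object bundles
#' the cdf, pdf, log-pdf and quantile function of that law together with its
#' parameter vector, so the generic transform ([ptiht()], [dtiht()], ...) can
#' be applied to any lifetime baseline.
#'
#' For deep-tail accuracy the object can also carry `log_sf(x)` (log survival
#' function) and `quantile_lsf(ls)` (quantile as a function of the log
#' survival level); when absent, numerically weaker fallbacks built from `cdf`
#' and `quantile` are used.
#'
#' @param name Identifier for the baseline family.
#' @param params Named numeric vector of baseline parameters (all positive for
#'   the lifetime baselines shipped here).
#' @param cdf,pdf,log_pdf,quantile Vectorised functions of `x` (or `u` for the
#'   quantile) implementing the baseline law. `log_pdf` defaults to
#'   `log(pdf(x))`.
#' @param log_sf Optional vectorised log survival function; defaults to
#'   `log1p(-cdf(x))`.
#' @param quantile_lsf Optional quantile as a function of log survival
#'   `ls = log(1 - u)`; defaults to `quantile(-expm1(ls))`.
#' @param support_lower Lower end of the support (0 for lifetime baselines).
#'
#' @return An object of class `tiht_baseline`.
#'
#' @examples
#' b <- baseline_weibull(alpha = 2, gamma = 1)
#' b$cdf(1)
#' @export
baseline_distribution <- function(name, params, cdf, pdf,
                                  log_pdf = NULL, quantile,
                                  log_sf = NULL, quantile_lsf = NULL,
                                  support_lower = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(log_pdf)) log_pdf <- function(x) log(pdf(x))
  if (is.null(log_sf)) log_sf <- function(x) log1p(-cdf(x))
  if (is.null(quantile_lsf)) {
    qf <- quantile
    quantile_lsf <- function(ls) qf(-expm1(ls))
  }
  structure(
    list(
      name = name, params = params,
      cdf = cdf, pdf = pdf, log_pdf = log_pdf, quantile = quantile,
      log_sf = log_sf, quantile_lsf = quantile_lsf,
      support_lower = support_lower
    ),
    class = "tiht_baseline"
  )
}

#' @export
print.tiht_baseline <- function(x, ...) {
  cat(sprintf(
    "<tiht_baseline> %s(%s)\n", x$name,
    paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", ")
  ))
  invisible(x)
}

#' Weibull baseline in rate form
#'
#' The Weibull baseline used throughout, in its *rate* parameterization
#' `F(x) = 1 - exp(-gamma * x^alpha)` (`gamma` multiplies `x^alpha` directly;
#' it is not a scale). [weibull_rate_to_scale()] and
#' [weibull_scale_to_rate()] convert between this and the `(shape, scale)`
#' form used by [stats::dweibull()].
#'
#' @param alpha Shape parameter, `> 0`.
#' @param gamma Rate-type parameter, `> 0`.
#' @return A [baseline_distribution()] object.
#' @examples
#' b <- baseline_weibull(2, 1)
#' b$quantile(0.5)^2 # log(2)
#' @export
baseline_weibull <- function(alpha, gamma) {
  check_pos(alpha, "alpha")
  check_pos(gamma, "gamma")
  baseline_distribution(
    name = "weibull",
    params = c(alpha = alpha, gamma = gamma),
    cdf = function(x) ifelse(x <= 0, 0, -expm1(-gamma * x^alpha)),
    pdf = function(x) ifelse(x <= 0, 0,
      alpha * gamma * x^(alpha - 1) * exp(-gamma * x^alpha)
    ),
    log_pdf = function(x) ifelse(x <= 0, -Inf,
      log(alpha) + log(gamma) + (alpha - 1) * log(x) - gamma * x^alpha
    ),
    quantile = function(u) (-log1p(-u) / gamma)^(1 / alpha),
    log_sf = function(x) ifelse(x <= 0, 0, -gamma * x^alpha),
    quantile_lsf = function(ls) (-ls / gamma)^(1 / alpha),
    support_lower = 0
  )
}

#' @rdname baseline_weibull
#' @param scale Weibull scale parameter of the `(x/scale)^shape` form.
#' @export
weibull_scale_to_rate <- function(alpha, scale) {
  check_pos(alpha, "alpha")
  check_pos(scale, "scale")
  c(alpha = alpha, gamma = scale^(-alpha))
}

#' @rdname baseline_weibull
#' @export
weibull_rate_to_scale <- function(alpha, gamma) {
  check_pos(alpha, "alpha")
  check_pos(gamma, "gamma")
  c(shape = alpha, scale = gamma^(-1 / alpha))
}
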