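#' Value at risk and tail value at risk of the TI-HTW distribution
#'
#' `var_tihtw()` evaluates the closed-form quantile
#' \deqn{VaR_q = \left[-\frac{1}{\gamma}\log\left\{1 -
#'   \frac{(1-q)^{1/\theta}-1}{(1-\theta)(1-q)^{1/\theta}-1}\right\}
#'   \right]^{1/\alpha},}
#' i.e. the q-quantile of the loss distribution. `tvar_tihtw()` computes the
#' expected loss beyond that level,
#' \eqn{TVaR_q = E[X \mid X > VaR_q]}.
#'
#' The canonical TVaR method substitutes `u = G(x)` so the semi-infinite tail
#' integral becomes \eqn{\int_q^1 Q(u)\,du/(1-q)}, avoiding any domain
#' truncation. The `"series"` method instead expands the tail integral into
#' upper-incomplete-gamma terms: each `(i, j, k)` term is
#' \deqn{\theta^2 (-1)^{j+k} (1-\theta)^i \binom{\theta-1}{j}
#'   \binom{i+\theta}{\theta} \binom{i+j}{k}
#'   \frac{\Gamma(1/\alpha + 1,\ \gamma(k+1)VaR_q^\alpha)}
#'   {(k+1)\,\{\gamma(k+1)\}^{1/\alpha}\,(1-q)}.}
#' The alternating inner k-sum is an (i+j)-th finite difference and loses
#' roughly `2^(i+j)` ulps, so beyond `m = i + j = 30` the tail integral
#' \eqn{\int_{VaR_q}^\infty x f F^m dx} is evaluated by quadrature instead.
#' The series requires `theta` in (0, 2).
#'
#' @param q Significance level(s) in (0, 1) (TVaR also accepts `q = 0`,
#'   giving the mean).
#' @param alpha,gamma,theta TI-HTW parameters, all `> 0`.
#' @param method `"quadrature"` (canonical) or `"series"` for TVaR.
#' @param i_max,tol Series truncation controls (as in
#'   [tihtw_moment_series()]).
#'
#' @return Numeric vector the length of `q`.
#' @examples
#' var_tihtw(0.95, 1.2, 0.7, 0.9)
#' tvar_tihtw(0.95, 1.2, 0.7, 0.9)
#' @export
var_tihtw <- function(q, alpha, gamma, theta) {
  check_tihtw(alpha, gamma, theta)
  if (any(q <= 0 | q >= 1)) {
    abort("`q` must lie strictly in (0, 1): VaR -> 0 as q -> 0 and -> Inf as q -> 1.")
  }
  qtihtw(q, alpha, gamma, theta)
}

#' @rdname var_tihtw
#' @export
tvar_tihtw <- function(q, alpha, gamma, theta,
                       method = c("quadrature", "series"),
                       i_max = 500L, tol = 1e-12) {
  check_tihtw(alpha, gamma, theta)
  method <- match.arg(method)
  if (any(q < 0 | q >= 1)) abort("`q` must lie in [0, 1).")
  vapply(q, function(qi) {
    switch(method,
      quadrature = tvar_quad(qi, alpha, gamma, theta),
      series = tvar_series(qi, alpha, gamma, theta, i_max, tol)
    )
  }, numeric(1))
}

tvar_quad <- function(q, alpha, gamma, theta) {
  out <- integrate(function(u) qtihtw(u, alpha, gamma, theta),
                   lower = q, upper = 1,
                   rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 500L)
  if (out$message != "OK") {
    abort(sprintf("tail quadrature did not converge: %s", out$message))
  }
  out$value / (1 - q)
}

# upper tail integral int_v^Inf x f(x) F(x)^m dx for the Weibull baseline:
# incomplete-gamma binomial sum for small integer m (the alternating sum is
# an m-th finite difference, unusable much past m = 30 in double precision),
# substituted quadrature beyond the cap and for the real-m tail completion
tail_kappa <- function(m, v, alpha, gamma, gamma_cap = 30L) {
  if (m <= gamma_cap && m == round(m)) {
    k <- 0:m
    a <- 1 / alpha + 1
    z <- gamma * (k + 1) * v^alpha
    terms <- choose(m, k) * (-1)^k *
      (gamma * (k + 1))^(-1 / alpha) / (k + 1) *
      base::gamma(a) * pgamma(z, a, lower.tail = FALSE)
    sum(terms)
  } else {
    weibull_kappa(1, m, alpha, gamma, v = v)
  }
}

tvar_series <- function(q, alpha, gamma, theta, i_max, tol) {
  if (theta <= 0 || theta >= 2) {
    abort("the series TVaR requires theta in (0, 2); use method = 'quadrature'.")
  }
  v <- if (q == 0) 0 else var_tihtw(q, alpha, gamma, theta)
  if (abs(theta - 1) < 1e-12) {
    return(tail_kappa(0, v, alpha, gamma) / (1 - q))
  }
  s <- tiht_series_sum(theta, function(m) tail_kappa(m, v, alpha, gamma),
                       i_max = i_max, tol = tol)
  s$value / (1 - q)
}

#' @importFrom stats pgamma
NULL
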