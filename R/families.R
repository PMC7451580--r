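#' Competitor loss distributions
#'
#' Closed-form density, distribution and quantile functions for the
#' comparison families used alongside TI-HTW in model discrimination:
#' the exponentiated Weibull (EW, cdf `(1 - e^(-gamma x^alpha))^theta_e`),
#' Lomax (cdf `1 - (1 + x/lambda)^(-alpha)`) and two-parameter Burr-XII
#' (cdf `1 - (1 + x^c)^(-k)`). All use the same rate-form Weibull kernel as
#' the rest of the package where applicable.
#'
#' @param x,q Evaluation points.
#' @param p Probabilities in `[0, 1)`.
#' @param alpha,gamma,theta_e,lambda,c,k Strictly positive parameters.
#' @param log,log.p,lower.tail As in the base distribution functions.
#' @name competitors
NULL

#' @rdname competitors
#' @export
dew <- function(x, alpha, gamma, theta_e, log = FALSE) {
  check_pos(alpha, "alpha"); check_pos(gamma, "gamma"); check_pos(theta_e, "theta_e")
  ld <- ifelse(x <= 0, -Inf,
    base::log(theta_e) + base::log(alpha) + base::log(gamma) +
      (alpha - 1) * base::log(x) - gamma * x^alpha +
      (theta_e - 1) * base::log(-expm1(-gamma * x^alpha))
  )
  if (log) ld else exp(ld)
}

#' @rdname competitors
#' @export
pew <- function(q, alpha, gamma, theta_e, lower.tail = TRUE, log.p = FALSE) {
  lp <- ifelse(q <= 0, -Inf, theta_e * base::log(-expm1(-gamma * q^alpha)))
  if (lower.tail) {
    if (log.p) lp else exp(lp)
  } else {
    out <- -expm1(lp)
    if (log.p) log(out) else out
  }
}

#' @rdname competitors
#' @export
qew <- function(p, alpha, gamma, theta_e) {
  (-log1p(-p^(1 / theta_e)) / gamma)^(1 / alpha)
}

#' @rdname competitors
#' @export
dlomax <- function(x, alpha, lambda, log = FALSE) {
  ld <- ifelse(x < 0, -Inf,
    base::log(alpha) - base::log(lambda) - (alpha + 1) * log1p(x / lambda)
  )
  if (log) ld else exp(ld)
}

#' @rdname competitors
#' @export
plomax <- function(q, alpha, lambda, lower.tail = TRUE, log.p = FALSE) {
  lsf <- ifelse(q < 0, 0, -alpha * log1p(q / lambda))
  if (lower.tail) {
    out <- -expm1(lsf)
    if (log.p) log(out) else out
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname competitors
#' @export
qlomax <- function(p, alpha, lambda) lambda * expm1(-log1p(-p) / alpha)

#' @rdname competitors
#' @export
dburr12 <- function(x, c, k, log = FALSE) {
  ld <- ifelse(x <= 0, -Inf,
    base::log(c) + base::log(k) + (c - 1) * base::log(x) -
      (k + 1) * log1p(x^c)
  )
  if (log) ld else exp(ld)
}

#' @rdname competitors
#' @export
pburr12 <- function(q, c, k, lower.tail = TRUE, log.p = FALSE) {
  lsf <- ifelse(q <= 0, 0, -k * log1p(q^c))
  if (lower.tail) {
    out <- -expm1(lsf)
    if (log.p) log(out) else out
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname competitors
#' @export
qburr12 <- function(p, c, k) expm1(-log1p(-p) / k)^(1 / c)

# ---------------------------------------------------------------------------
# family registry: every fittable family exposes the same surface
# (logpdf / cdf / quantile / start), keyed by a lowercase identifier.
# ---------------------------------------------------------------------------

family_registry <- function() {
  list(
    tihtw = list(
      label = "TI-HTW", par_names = c("alpha", "gamma", "theta"),
      logpdf = function(x, p) dtihtw(x, p[1], p[2], p[3], log = TRUE),
      cdf = function(x, p) ptihtw(x, p[1], p[2], p[3]),
      quantile = function(u, p) qtihtw(u, p[1], p[2], p[3]),
      start = function(x) c(weibull_start(x), theta = 1)
    ),
    tihte = list(
      label = "TI-HTE", par_names = c("gamma", "theta"),
      logpdf = function(x, p) dtihtw(x, 1, p[1], p[2], log = TRUE),
      cdf = function(x, p) ptihtw(x, 1, p[1], p[2]),
      quantile = function(u, p) qtihtw(u, 1, p[1], p[2]),
      start = function(x) c(gamma = 1 / mean(x), theta = 1)
    ),
    tihtr = list(
      label = "TI-HTR", par_names = c("gamma", "theta"),
      logpdf = function(x, p) dtihtw(x, 2, p[1], p[2], log = TRUE),
      cdf = function(x, p) ptihtw(x, 2, p[1], p[2]),
      quantile = function(u, p) qtihtw(u, 2, p[1], p[2]),
      start = function(x) c(gamma = length(x) / sum(x^2), theta = 1)
    ),
    weibull = list(
      label = "Weibull", par_names = c("alpha", "gamma"),
      logpdf = function(x, p) {
        ifelse(x <= 0, -Inf,
          base::log(p[1]) + base::log(p[2]) + (p[1] - 1) * base::log(x) -
            p[2] * x^p[1]
        )
      },
      cdf = function(x, p) ifelse(x <= 0, 0, -expm1(-p[2] * x^p[1])),
      quantile = function(u, p) (-log1p(-u) / p[2])^(1 / p[1]),
      start = weibull_start
    ),
    ew = list(
      label = "EW", par_names = c("alpha", "gamma", "theta_e"),
      logpdf = function(x, p) dew(x, p[1], p[2], p[3], log = TRUE),
      cdf = function(x, p) pew(x, p[1], p[2], p[3]),
      quantile = function(u, p) qew(u, p[1], p[2], p[3]),
      start = function(x) c(weibull_start(x), theta_e = 1)
    ),
    lomax = list(
      label = "Lomax", par_names = c("alpha", "lambda"),
      logpdf = function(x, p) dlomax(x, p[1], p[2], log = TRUE),
      cdf = function(x, p) plomax(x, p[1], p[2]),
      quantile = function(u, p) qlomax(u, p[1], p[2]),
      start = function(x) c(alpha = 2, lambda = mean(x))
    ),
    burr12 = list(
      label = "Burr-XII", par_names = c("c", "k"),
      logpdf = function(x, p) dburr12(x, p[1], p[2], log = TRUE),
      cdf = function(x, p) pburr12(x, p[1], p[2]),
      quantile = function(u, p) qburr12(u, p[1], p[2]),
      start = function(x) c(c = max(pi / (sqrt(3) * sd(log(x))), 0.2), k = 1)
    )
  )
}

# moment-of-log heuristic: sd(log X) = pi / (sqrt(6) alpha) for the Weibull,
# then the rate MLE given the shape
weibull_start <- function(x) {
  a0 <- pi / (sqrt(6) * max(sd(log(x)), 1e-3))
  a0 <- min(max(a0, 0.05), 50)
  c(alpha = a0, gamma = length(x) / sum(x^a0))
}

#' Look up a fittable family by identifier
#'
#' @param family One of `"tihtw"`, `"tihte"`, `"tihtr"`, `"weibull"`, `"ew"`,
#'   `"lomax"`, `"burr12"`.
#' @return A list with `label`, `par_names`, and `logpdf`/`cdf`/`quantile`/
#'   `start` functions taking the parameter vector in `par_names` order.
#' @examples
#' fam <- get_family("lomax")
#' fam$cdf(1, c(1, 1)) # 0.5
#' @export
get_family <- function(family) {
  reg <- family_registry()
  if (!family %in% names(reg)) {
    abort(sprintf(
      "unknown family '%s'; available: %s",
      family, paste(names(reg), collapse = ", ")
    ))
  }
  reg[[family]]
}
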