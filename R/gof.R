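#' Discrimination and goodness-of-fit measures
#'
#' `discrimination_measures()` returns the Akaike and Bayesian information
#' criteria of a fitted model (`AIC = -2 l + 2k`, `BIC = -2 l + k log n`).
#'
#' `edf_statistics()` computes the empirical-distribution-function statistics
#' of a fitted cdf on a sample: with `u_i = cdf(x_(i))` on the sorted sample,
#' \deqn{CM = \frac{1}{12n} + \sum_i \left(u_i - \frac{2i-1}{2n}\right)^2,}
#' \deqn{AD = -n - \frac{1}{n}\sum_i (2i-1)\{\log u_i + \log(1-u_{n+1-i})\},}
#' \deqn{KS = \max\left(\max_i\left(\frac{i}{n}-u_i\right),
#'   \max_i\left(u_i-\frac{i-1}{n}\right)\right),}
#' with the KS p-value from the asymptotic Kolmogorov distribution. That
#' p-value is *not* adjusted for estimated parameters and is therefore
#' liberal (biased towards large p) when the cdf was fitted to the same data
#' — the usual convention in model-comparison tables for this family of
#' analyses, but not a calibrated test.
#'
#' @param fit A `tiht_fit` object.
#' @param data Positive sample vector.
#' @param fitted_cdf Vectorised cdf function (already parameterized).
#' @return `discrimination_measures()`: a named list `aic`, `bic`;
#'   `edf_statistics()`: a named list `cm`, `ad`, `ks`, `ks_pvalue`.
#' @examples
#' x <- rtihtw(100, 1.4, 1, 0.9, seed = 3)
#' f <- fit_mle(x, "weibull")
#' discrimination_measures(f)
#' @export
discrimination_measures <- function(fit) {
  stopifnot(inherits(fit, "tiht_fit"))
  list(aic = fit$aic, bic = fit$bic)
}

#' @rdname discrimination_measures
#' @export
edf_statistics <- function(data, fitted_cdf) {
  check_sample(data)
  n <- length(data)
  u <- fitted_cdf(sort(data))
  if (any(u <= 0 | u >= 1)) {
    warn("fitted cdf hit 0 or 1 on the data; values nudged to the interior.")
    eps <- .Machine$double.xmin
    u <- pmin(pmax(u, eps), 1 - .Machine$double.eps)
  }
  i <- seq_len(n)
  cm <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  ad <- -n - mean((2 * i - 1) * (base::log(u) + base::log(1 - u[n + 1 - i])))
  ks <- max(max(i / n - u), max(u - (i - 1) / n))
  list(cm = cm, ad = ad, ks = ks, ks_pvalue = kolmogorov_pvalue(ks, n))
}

# asymptotic Kolmogorov tail probability P(sqrt(n) D > sqrt(n) d)
kolmogorov_pvalue <- function(d, n) {
  x <- sqrt(n) * d
  if (x < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

#' Fit and rank candidate models on one dataset
#'
#' Fits every requested family by maximum likelihood and tabulates AIC, BIC,
#' Cramér-von Mises, Anderson-Darling and Kolmogorov-Smirnov (with p-value)
#' statistics, sorted by AIC (ties broken by BIC, then family name). Lower
#' values of every measure indicate the better candidate. A family that
#' fails to converge keeps its row with `converged = FALSE` and `NA`
#' measures rather than being dropped; non-finite EDF statistics propagate
#' as-is.
#'
#' @param data Positive sample vector.
#' @param families Character vector of at least two family identifiers.
#' @param level Confidence level passed to [fit_mle()].
#' @return A tibble with one row per family, invisibly carrying the fits in
#'   the `fits` attribute.
#' @examples
#' x <- rtihtw(150, 1.4, 0.03, 2, seed = 11)
#' compare_models(x, c("tihtw", "weibull", "lomax"))
#' @export
compare_models <- function(data, families, level = 0.95) {
  check_sample(data)
  if (length(families) < 2L) abort("supply at least two families to compare.")
  fits <- purrr::map(families, function(fam) {
    tryCatch(fit_mle(data, fam, level = level), error = function(e) NULL)
  })
  rows <- purrr::map2(families, fits, function(fam, fit) {
    lab <- get_family(fam)$label
    if (is.null(fit) || !fit$converged) {
      return(tibble(
        family = fam, label = lab, k_params = length(get_family(fam)$par_names),
        aic = NA_real_, bic = NA_real_, cm = NA_real_, ad = NA_real_,
        ks = NA_real_, ks_pvalue = NA_real_, converged = FALSE
      ))
    }
    reg <- get_family(fam)
    edf <- suppressWarnings(
      edf_statistics(data, function(x) reg$cdf(x, unname(fit$estimates)))
    )
    tibble(
      family = fam, label = lab, k_params = fit$k_params,
      aic = fit$aic, bic = fit$bic,
      cm = edf$cm, ad = edf$ad, ks = edf$ks, ks_pvalue = edf$ks_pvalue,
      converged = TRUE
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$converged), .data$aic,
                        .data$bic, .data$family)
  attr(out, "fits") <- setNames(fits, families)
  out
}
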