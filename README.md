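# tiht

Heavy-tailed lifetime distributions for survival, reliability and
insurance-loss data: the **type-I heavy-tailed (TI-HT) family** and its
Weibull special case, with maximum-likelihood and Bayesian fitting,
actuarial tail measures, Monte Carlo study harnesses and goodness-of-fit
model comparison.

## The model

Remission times, failure times and insurance losses are positive,
right-skewed, and often carry more probability deep in the right tail than
a Weibull or gamma fit allows. The TI-HT construction adds a single tail
parameter θ > 0 to any baseline lifetime cdf F(x; ξ):

    G(x) = 1 − [ (1 − F(x)) / (1 − (1 − θ) F(x)) ]^θ

θ = 1 returns the baseline exactly; θ < 1 thickens the tail, θ > 1 thins
it. With the rate-form Weibull baseline F(x) = 1 − exp(−γ xᵅ) this gives
the three-parameter **TI-HT-Weibull (TI-HTW)** distribution, which has
closed forms for the density, cdf, survival, hazard and quantile function
— so quantile-inversion sampling, value at risk (VaR_q, the q-quantile of
the loss) and tail value at risk (TVaR_q = E[X | X > VaR_q]) are all
cheap and exact.

## What the package provides

* `d/p/q/r/s/htihtw()` — closed-form TI-HTW evaluators; `d/p/q/r/s/htiht()`
  apply the transform to any `baseline_distribution()`;
  `reduce_special_case()` names the nested sub-models.
* `fit_mle()` — maximum likelihood with analytic score, observed-information
  standard errors and (untruncated) Wald intervals; broom-style `tidy()` /
  `glance()` and `autoplot()` methods.
* `tiht_moment()`, `tiht_describe()`, `tihtw_moment_series()`, `tiht_mgf()`
  — moments by adaptive quadrature (canonical) and by the family's series
  expansion (cross-check).
* `var_tihtw()`, `tvar_tihtw()` — closed-form VaR; TVaR by tail quadrature
  or incomplete-gamma series.
* `run_mle_simulation()`, `run_risk_simulation()` — the bias/MSE/coverage
  and VaR/TVaR Monte Carlo harnesses, fully seeded and reproducible.
* `compare_models()`, `edf_statistics()` — AIC/BIC/Cramér–von Mises/
  Anderson–Darling/Kolmogorov–Smirnov comparison against Weibull,
  exponentiated Weibull, Lomax and Burr-XII competitors.
* `mcmc_sample()`, `gelman_rubin()`, `dic()` — adaptive random-walk
  Metropolis under diffuse gamma priors, with convergence diagnostics and
  DIC model comparison.
* `read_sample_csv()`, `generate_fixture()` and a thin CLI
  (`inst/cli/tiht.R`) with `fit | simulate | risk | gof | bayes | fixture`
  subcommands.

## A worked example

```r
library(tiht)

# simulate a heavy-tailed sample and fit the model and its Weibull null
x   <- rtihtw(500, alpha = 1.4, gamma = 0.03, theta = 0.2, seed = 42)
fit <- fit_mle(x, "tihtw")
tidy(fit)
#> # A tibble: 3 × 5
#>   term  estimate std.error conf.low conf.high
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 alpha   1.37      0.0498   1.27      1.47
#> 2 gamma   0.0339    0.0117   0.0110    0.0568
#> 3 theta   0.204     0.0517   0.103     0.305

compare_models(x, c("tihtw", "weibull", "lomax", "burr12"))
#>      label  aic  bic       cm       ad      ks ks_pvalue
#> 1   TI-HTW 4532 4544  0.04003   0.3545 0.02035  9.86e-01
#> 2  Weibull 4540 4549  0.18635   1.2151 0.04589  2.43e-01
#> 3    Lomax 4759 4767  7.78514  41.2536 0.21584  1.17e-20
#> 4 Burr-XII 5839 5847 32.41777 152.1158 0.45454  3.74e-90

# the fitted tail: 99% value at risk and the expected loss beyond it
var_tihtw(0.99, 1.37, 0.0339, 0.204)
#> [1] 120.4
tvar_tihtw(0.99, 1.37, 0.0339, 0.204)
#> [1] 137.5
```

The estimates recover the generating values (1.4, 0.03, 0.2) within their
intervals; TI-HTW beats all three competitors on every measure (smaller is
better for AIC/BIC/CM/AD/KS, larger for the KS p-value); and the tail
measures quantify what the extra parameter buys — the fitted 99% VaR is
about 120 where the Weibull fit to the same data implies about 112, with
the gap widening further into the tail.

(Output abbreviated to display precision; `seed = 42` reproduces it
exactly.)

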