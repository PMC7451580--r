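test_that("closed-form TI-HTW evaluators match the generic transform", {
  set.seed(3)
  for (i in 1:20) {
    par <- c(runif(1, 0.3, 3), runif(1, 0.1, 2), runif(1, 0.2, 2.5))
    b <- baseline_weibull(par[1], par[2])
    x <- runif(5, 0.01, 8)
    u <- runif(5, 0, 0.999)
    expect_equal(ptihtw(x, par[1], par[2], par[3]), ptiht(x, par[3], b),
                 tolerance = 1e-13)
    expect_equal(dtihtw(x, par[1], par[2], par[3]), dtiht(x, par[3], b),
                 tolerance = 1e-13)
    expect_equal(qtihtw(u, par[1], par[2], par[3]), qtiht(u, par[3], b),
                 tolerance = 1e-13)
  }
})

test_that("density is nonnegative and unimodal-or-decreasing on a grid", {
  x <- seq(0.001, 10, length.out = 2000)
  d <- dtihtw(x, 1.4, 1, 0.9)
  expect_true(all(d >= 0))
  sgn <- sign(diff(d))
  expect_lte(sum(diff(sgn[sgn != 0]) != 0), 1) # at most one turning point
})

test_that("named special cases reduce as documented", {
  expect_equal(reduce_special_case(2, 0.5, 1),
               list(model = "rayleigh", params = c(gamma = 0.5)))
  expect_equal(reduce_special_case(1, 2, 3),
               list(model = "tihte", params = c(theta = 3, gamma = 2)))
  expect_equal(reduce_special_case(2, 2, 3),
               list(model = "tihtr", params = c(theta = 3, gamma = 2)))
  expect_equal(reduce_special_case(1.4, 1, 0.9)$model, "tihtw")
  expect_equal(reduce_special_case(1.3, 0.7, 1)$model, "weibull")
  expect_equal(reduce_special_case(1.3, 1, 1)$model, "weibull1")
  expect_equal(reduce_special_case(1, 0.7, 1)$model, "exponential")
})

test_that("competitor families are proper distributions", {
  cases <- list(
    ew = list(d = function(x) dew(x, 1.3, 0.8, 1.7),
              q = function(u) qew(u, 1.3, 0.8, 1.7),
              p = function(x) pew(x, 1.3, 0.8, 1.7)),
    lomax = list(d = function(x) dlomax(x, 2.5, 1.4),
                 q = function(u) qlomax(u, 2.5, 1.4),
                 p = function(x) plomax(x, 2.5, 1.4)),
    burr12 = list(d = function(x) dburr12(x, 1.8, 2.2),
                  q = function(u) qburr12(u, 1.8, 2.2),
                  p = function(x) pburr12(x, 1.8, 2.2))
  )
  u <- c(0.001, 0.1, 0.5, 0.9, 0.999)
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    expect_equal(integrate(cs$d, 0, Inf, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6, label = paste(nm, "pdf mass"))
    expect_equal(cs$p(cs$q(u)), u, tolerance = 1e-9,
                 label = paste(nm, "round trip"))
  }
  # closed-form anchors
  expect_equal(plomax(1.4, 1, 1.4), 0.5, tolerance = 1e-12)
  x <- c(0.2, 1, 3)
  expect_equal(pew(x, 1.3, 0.8, 1), -expm1(-0.8 * x^1.3), tolerance = 1e-14)
})

test_that("the family registry exposes a uniform fit surface", {
  fams <- c("tihtw", "tihte", "tihtr", "weibull", "ew", "lomax", "burr12")
  x <- rtihtw(60, 1.2, 1, 0.8, seed = 5)
  for (f in fams) {
    reg <- get_family(f)
    expect_named(reg$start(x), reg$par_names, label = f)
    p0 <- unname(reg$start(x))
    expect_true(all(is.finite(reg$logpdf(x, p0))), label = f)
    expect_equal(reg$cdf(reg$quantile(0.37, p0), p0), 0.37,
                 tolerance = 1e-9, label = f)
  }
  expect_error(get_family("cauchy"), "unknown family")
})

test_that("rate/scale Weibull conversions invert each other", {
  rs <- weibull_rate_to_scale(1.6, 0.4)
  back <- weibull_scale_to_rate(rs[["shape"]], rs[["scale"]])
  expect_equal(unname(back), c(1.6, 0.4), tolerance = 1e-14)
  expect_equal(pweibull(2, rs[["shape"]], rs[["scale"]]),
               ptihtw(2, 1.6, 0.4, 1), tolerance = 1e-14)
})
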