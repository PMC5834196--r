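# Hazard families, cumulative hazards, survivor functions, frailty
# marginals, and the rate of aging.

test_that("hazard closed forms are exact", {
  expect_equal(hazard(hazard_family("weibull", lambda = 0.01, k = 1), 17),
               0.01)
  expect_equal(hazard(hazard_family("weibull", lambda = 2, k = 2), 3), 12)
  expect_equal(hazard(hazard_family("gompertz", a = 0.001, b = 0.1), 0),
               0.001)
  expect_equal(
    hazard(hazard_family("gompertz_makeham", a = 0.001, b = 0.1, c = 0.02),
           10),
    0.02 + 0.001 * exp(1))
  expect_error(hazard(hazard_family("weibull", lambda = 1, k = 0.5), 0),
               "singular")
  expect_error(hazard_family("weibull", lambda = -1, k = 1), "lambda")
  expect_error(hazard_family("gompertz_makeham", a = 1, b = 0.1, c = -1),
               "c must be")
})

test_that("cumulative hazard agrees with numerical integration", {
  set.seed(42)
  fams <- list(
    hazard_family("weibull", lambda = 0.03, k = 1.4),
    hazard_family("weibull", lambda = 0.2, k = 0.8),
    hazard_family("gompertz", a = 1e-4, b = 0.09),
    hazard_family("gompertz_makeham", a = 1e-4, b = 0.09, c = 0.01),
    hazard_family("weibull_makeham", lambda = 0.02, k = 1.3, c = 0.015))
  for (f in fams) for (x in c(2.5, 40, 77)) {
    quad <- stats::integrate(function(t) hazard(f, t), 0, x,
                             rel.tol = 1e-11)$value
    expect_equal(cumulative_hazard(f, x), quad, tolerance = 1e-8)
  }
  # exponential special case and the b -> 0 Gompertz limit
  expect_equal(cumulative_hazard(hazard_family("weibull", lambda = 0.5,
                                               k = 1), 2), 1.0)
  expect_equal(cumulative_hazard(hazard_family("gompertz", a = 0.02,
                                               b = 0), 30), 0.6)
  expect_equal(cumulative_hazard(hazard_family("gompertz", a = 0.02,
                                               b = 1e-14), 30),
               0.6, tolerance = 1e-9)
})

test_that("survivor function is exp(-cumhaz), starts at 1, non-increasing", {
  set.seed(7)
  for (rep in 1:5) {
    f <- hazard_family("weibull", lambda = runif(1, 0.01, 0.3),
                       k = runif(1, 0.7, 2))
    x <- seq(0, 90, by = 0.5)
    S <- survivor(f, x)
    expect_equal(S, exp(-cumulative_hazard(f, x)))
    expect_equal(S[1], 1)
    expect_true(all(diff(S) <= 0))
  }
  expect_equal(survivor(hazard_family("weibull", lambda = 1, k = 1), 1),
               exp(-1))
})

test_that("hazard equals -d/dx log survivor by central differences", {
  set.seed(11)
  fams <- list(
    hazard_family("weibull", lambda = 0.05, k = 1.3),
    hazard_family("gompertz", a = 2e-4, b = 0.08),
    hazard_family("gompertz_makeham", a = 2e-4, b = 0.08, c = 0.01),
    hazard_family("weibull_makeham", lambda = 0.04, k = 0.9, c = 0.02))
  for (f in fams) for (x in runif(4, 1, 90)) {
    h <- 1e-5 * max(1, x)
    num <- -(log(survivor(f, x + h)) - log(survivor(f, x - h))) / (2 * h)
    expect_equal(hazard(f, x), num, tolerance = 1e-6)
  }
})

test_that("gamma and inverse-Gaussian frailty marginals match closed and quadrature forms", {
  f <- hazard_family("weibull", lambda = 1, k = 1)
  # gamma sigma2=1 at Lambda=1: (1+1)^-1
  expect_equal(frailty_marginal_survival(f, frailty_spec("gamma", 1), 1),
               0.5)
  expect_equal(frailty_marginal_hazard(f, frailty_spec("gamma", 1), 1),
               0.5)
  # inverse-Gaussian marginal vs direct integration over the IG density
  s2 <- 0.6
  dig <- function(z) sqrt(1 / (2 * pi * s2 * z^3)) *
    exp(-(z - 1)^2 / (2 * s2 * z))
  for (L in c(0.3, 1.2, 3)) {
    quad <- stats::integrate(function(z) dig(z) * exp(-z * L), 0, Inf,
                             rel.tol = 1e-10)$value
    fam <- hazard_family("weibull", lambda = L, k = 1)
    expect_equal(
      frailty_marginal_survival(fam, frailty_spec("inverse_gaussian", s2), 1),
      quad, tolerance = 1e-7)
  }
})

test_that("log-normal frailty marginal agrees with Monte-Carlo mixing", {
  f <- hazard_family("weibull", lambda = 0.03, k = 1.3)
  fr <- frailty_spec("log_normal", 0.5)
  set.seed(99)
  w2 <- log(1 + 0.5)
  z <- exp(rnorm(1e6, -w2 / 2, sqrt(w2)))
  expect_equal(mean(z), 1, tolerance = 0.005)
  for (x in c(30, 60)) {
    L <- cumulative_hazard(f, x)
    draws <- exp(-z * L)
    mc <- mean(draws)
    mc_se <- sd(draws) / sqrt(length(z))
    est <- frailty_marginal_survival(f, fr, x)
    expect_lt(abs(est - mc), 3 * mc_se + 1e-10)
  }
})

test_that("frailty mixing raises population survival and vanishes as sigma2 -> 0", {
  f <- hazard_family("gompertz", a = 1e-4, b = 0.1)
  x <- seq(1, 90, by = 1)
  for (dist in c("gamma", "inverse_gaussian", "log_normal")) {
    Sm <- frailty_marginal_survival(f, frailty_spec(dist, 0.8), x)
    expect_true(all(Sm >= survivor(f, x) - 1e-12))
    # sigma2 -> 0 continuity
    S0 <- frailty_marginal_survival(f, frailty_spec(dist, 1e-10), x)
    expect_lt(max(abs(S0 - survivor(f, x))), 1e-6)
    h0 <- frailty_marginal_hazard(f, frailty_spec(dist, 0), x)
    expect_equal(h0, hazard(f, x))
  }
})

test_that("marginal hazard is the negative log-derivative of marginal survival", {
  f <- hazard_family("weibull", lambda = 0.04, k = 1.2)
  for (dist in c("gamma", "inverse_gaussian", "log_normal")) {
    fr <- frailty_spec(dist, 0.7)
    for (x in c(35, 55, 80)) {
      h <- 1e-5 * x
      num <- -(log(frailty_marginal_survival(f, fr, x + h)) -
                 log(frailty_marginal_survival(f, fr, x - h))) / (2 * h)
      expect_equal(frailty_marginal_hazard(f, fr, x), num,
                   tolerance = 1e-5)
    }
  }
})

test_that("rate of aging closed forms and numeric consistency", {
  x <- c(31, 45.5, 69)
  expect_equal(rate_of_aging(hazard_family("gompertz", a = 1e-4, b = 0.1),
                             x), rep(0.1, 3))
  expect_equal(rate_of_aging(hazard_family("weibull", lambda = 0.05,
                                           k = 1.4), x), 0.4 / x)
  expect_equal(rate_of_aging(hazard_family("weibull", lambda = 0.05,
                                           k = 1), x), rep(0, 3))
  expect_true(all(rate_of_aging(hazard_family("weibull", lambda = 0.05,
                                              k = 0.96), x) < 0))
  # central-difference check including makeham and frailty cases
  cases <- list(
    list(f = hazard_family("gompertz_makeham", a = 1e-4, b = 0.1,
                           c = 0.01), fr = NULL),
    list(f = hazard_family("weibull_makeham", lambda = 0.03, k = 1.3,
                           c = 0.02), fr = NULL),
    list(f = hazard_family("weibull", lambda = 0.03, k = 1.3),
         fr = frailty_spec("gamma", 0.5)))
  for (cs in cases) for (xx in c(40, 60)) {
    h <- 1e-5 * xx
    num <- (log(hazard(cs$f, xx + h, cs$fr)) -
              log(hazard(cs$f, xx - h, cs$fr))) / (2 * h)
    expect_equal(rate_of_aging(cs$f, xx, cs$fr), num, tolerance = 1e-5)
  }
})
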