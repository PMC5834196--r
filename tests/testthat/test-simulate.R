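# Synthetic-data generator: determinism, distributional correctness,
# censoring mechanics, piecewise continuity, summaries.

test_that("generation is deterministic given a seed", {
  cfg <- generator_config(n_patients = 200, seed = 51)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(cfg, seed = 52)
  expect_false(identical(c1$exit_age_x, c3$exit_age_x))
})

test_that("inverse-transform sampling inverts closed forms", {
  # exponential: S(t) = e^(-t)
  expect_equal(inverse_transform_sample(exp(-2), "weibull",
                                        c(lambda = 1, k = 1)), 2)
  # weibull: t = (-log u / lambda)^(1/k)
  u <- 0.37
  expect_equal(inverse_transform_sample(u, "weibull",
                                        c(lambda = 0.2, k = 1.7)),
               (-log(u) / 0.2)^(1 / 1.7))
  # two-segment piecewise hazard vs a numeric root-find oracle
  params <- list(c(lambda = 0.5, k = 0.9), c(lambda = 0.1, k = 1.5))
  for (u in c(0.9, 0.5, 0.05)) {
    got <- inverse_transform_sample(u, "weibull", params, scale = c(1, 1.3),
                                    boundaries = 2, entry = 0.5)
    Lam <- function(t) {
      f1 <- hazard_family("weibull", lambda = 0.5, k = 0.9)
      f2 <- hazard_family("weibull", lambda = 0.1, k = 1.5)
      a <- cumulative_hazard(f1, min(t, 2)) - cumulative_hazard(f1, 0.5)
      b <- if (t > 2) 1.3 * (cumulative_hazard(f2, t) -
                               cumulative_hazard(f2, 2)) else 0
      a + b
    }
    oracle <- uniroot(function(t) Lam(t) + log(u), c(0.5000001, 500),
                      tol = 1e-13)$root
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("uncensored exponential means match the configured rate", {
  cfg <- generator_config(
    n_patients = 4000,
    stratum_params = list(all = c(lambda = 0.25, k = 1)),
    beta_true = NULL, censor_year = 3000, seed = 53)
  co <- generate_cohort(cfg)
  expect_true(all(co$event_theta == 1))
  t <- co$exit_age_x - co$transplant_age_j
  expect_lt(abs(mean(t) - 4), 3 * 4 / sqrt(4000))
})

test_that("generated times follow the analytic piecewise survival law", {
  cfg <- generator_config(n_patients = 2500, censor_year = 2300,
                          beta_true = NULL, seed = 54)
  co <- generate_cohort(cfg)
  dpy <- 365.25
  sp <- generator_config()$stratum_params
  for (d in c("related", "unrelated")) {
    sub <- co[co$donor_source == d, ]
    t <- sub$exit_age_x - sub$transplant_age_j
    j <- sub$transplant_age_j
    fam <- function(key) hazard_family("weibull",
                                       lambda = sp[[key]][["lambda"]],
                                       k = sp[[key]][["k"]])
    Hseg <- function(f, a, b) cumulative_hazard(f, b) -
      cumulative_hazard(f, a)
    b1 <- 100 / dpy; b2 <- 365 / dpy
    H <- Hseg(fam(paste0("I1.", d)), j, j + pmin(t, b1)) +
      ifelse(t > b1, Hseg(fam(paste0("I2.", d)), j + b1,
                          j + pmin(t, b2)), 0) +
      ifelse(t > b2, Hseg(fam(paste0("I3.", d)), j + b2, j + t), 0)
    ks <- suppressWarnings(stats::ks.test(exp(-H), "punif"))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("gamma-frailty generation matches the marginal conditional law", {
  cfg <- generator_config(
    n_patients = 3000,
    stratum_params = list(all = c(lambda = 0.04, k = 1.3)),
    beta_true = NULL, frailty_true = frailty_spec("gamma", 0.8),
    censor_year = 2300, seed = 55)
  co <- generate_cohort(cfg)
  fam <- hazard_family("weibull", lambda = 0.04, k = 1.3)
  fr <- frailty_spec("gamma", 0.8)
  u <- frailty_marginal_survival(fam, fr, co$exit_age_x) /
    frailty_marginal_survival(fam, fr, co$transplant_age_j)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("censoring is administrative at the calendar horizon", {
  cfg <- generator_config(n_patients = 1500, seed = 56)
  co <- generate_cohort(cfg)
  cens <- co[co$event_theta == 0, ]
  cal_exit <- cens$transplant_year + 0.5 +
    (cens$exit_age_x - cens$transplant_age_j)
  expect_equal(cal_exit, rep(2013, nrow(cens)), tolerance = 1e-9)
  # deaths never exceed the horizon
  dth <- co[co$event_theta == 1, ]
  expect_true(all(dth$transplant_year + 0.5 +
                    (dth$exit_age_x - dth$transplant_age_j) <= 2013 + 1e-9))
})

test_that("transplant ages respect the truncated support and year range", {
  co <- generate_cohort(generator_config(n_patients = 800, seed = 57))
  expect_true(all(co$transplant_age_j >= 30 &
                    co$transplant_age_j < 70))
  expect_true(all(co$transplant_year %in% 1995:2006))
})

test_that("summaries track the configured frequencies", {
  cfg <- generator_config(n_patients = 4000, seed = 58)
  co <- generate_cohort(cfg)
  sm <- summarize_cohort(co)
  n_rel <- sm$related$n
  expect_lt(abs(n_rel / 4000 - 3363 / 11160),
            3 * sqrt(0.301 * 0.699 / 4000))
  for (d in c("related", "unrelated")) {
    p <- cfg$covariate_freqs$acute_gvhd[[d]]
    n <- sm[[d]]$n
    expect_lt(abs(sm[[d]]$covariates$acute_gvhd[["yes"]] / 100 - p),
              3 * sqrt(p * (1 - p) / n))
  }
  # single-patient cohort puts 100% in one cell per dimension
  one <- as_cohort(as.data.frame(co[1, ]))
  s1 <- summarize_cohort(one)
  expect_equal(sum(s1$related$n, s1$unrelated$n), 1)
  expect_equal(max(s1[[co$donor_source[1]]]$interval_pct), 100)
})

test_that("degenerate configurations are rejected", {
  expect_error(generator_config(
    stratum_params = list(all = c(lambda = 0, k = 1))), "lambda")
  expect_error(generator_config(
    stratum_params = list(bogus = c(lambda = 1, k = 1))), "stratum_params")
  expect_error(generator_config(
    frailty_true = frailty_spec("gamma", 0.5)),
    "non-piecewise")
  expect_error(generator_config(
    stratum_params = list(all = c(lambda = 0.1, k = 1)),
    frailty_true = frailty_spec("gamma", 0.5),
    period_trend = -0.1), "period trend")
})
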