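# The modified stratified likelihood: delta matrix, individual
# contributions, truncation term, and the collapse identities.

# Independent brute-force oracle: log[h(x)^theta e^(theta*bZ)
# (S(x)/S(j))^(e^bZ)] written from first principles per record.
brute_loglik <- function(cohort, lambda, k, beta = 0) {
  z <- if ("acute_gvhd" %in% names(cohort)) cohort$acute_gvhd else 0
  tot <- 0
  for (i in seq_len(nrow(cohort))) {
    x <- cohort$exit_age_x[i]; j <- cohort$transplant_age_j[i]
    th <- cohort$event_theta[i]
    eta <- beta * z[i]
    logh <- log(lambda * k * x^(k - 1))
    logS <- -lambda * x^k
    logSj <- -lambda * j^k
    tot <- tot + th * (logh + eta) + exp(eta) * (logS - logSj)
  }
  tot
}

test_that("exponential closed-form contributions", {
  rec <- make_record("A", 1, 2, 1, ty = 2000)
  spec <- model_spec("weibull")
  params <- list(baseline = c(lambda = 1, k = 1))
  # theta=1: log h = 0, logS(2)-logS(1) = -1
  expect_equal(individual_loglik(rec, spec, params), -1)
  rec0 <- make_record("A", 1, 2, 0, ty = 2000)
  expect_equal(individual_loglik(rec0, spec, params), -1)
  # adding the death changes the contribution by exactly log h + beta z
  co <- sim_cohort(30, seed = 21)
  sp <- model_spec("weibull", covariates = "acute_gvhd")
  pp <- list(baseline = c(lambda = 0.05, k = 1.2),
             beta = c(acute_gvhd = 0.4))
  for (i in c(2, 17)) {
    r1 <- as.data.frame(co[i, ]); r1$event_theta <- 1
    r0 <- as.data.frame(co[i, ]); r0$event_theta <- 0
    gap <- individual_loglik(r1, sp, pp) - individual_loglik(r0, sp, pp)
    expect_equal(gap, log(0.05 * 1.2 * r1$exit_age_x^0.2) +
                   0.4 * r1$acute_gvhd)
  }
})

test_that("vectorized likelihood equals per-record brute force", {
  co <- sim_cohort(300, seed = 8)
  spec <- model_spec("weibull", covariates = "acute_gvhd")
  params <- list(baseline = c(lambda = 0.04, k = 1.25),
                 beta = c(acute_gvhd = 0.45))
  expect_equal(total_loglik(co, spec, params),
               brute_loglik(co, 0.04, 1.25, 0.45), tolerance = 1e-12)
})

test_that("delta matrix construction is one-hot with correct counts", {
  cfg <- generator_config(n_patients = 400, seed = 12)
  co <- generate_cohort(cfg)
  d <- build_delta(co, "interval_by_donor")
  expect_equal(ncol(d), 6)
  expect_true(all(rowSums(d) == 1))
  counts <- table(paste(co$interval, co$donor_source, sep = "."))
  expect_equal(colSums(d)[names(counts)], unclass(c(counts)),
               ignore_attr = TRUE)
  d0 <- build_delta(co, "none")
  expect_equal(dim(d0), c(400L, 1L))
  expect_true(all(d0 == 1))
})

test_that("all-ones delta collapses to the conventional pooled likelihood", {
  co <- sim_cohort(100, seed = 4)
  spec <- model_spec("weibull", stratification = "none")
  params <- list(baseline = c(lambda = 0.06, k = 1.1))
  plain <- total_loglik(co, spec, params)
  ones <- matrix(1L, nrow(co), 1, dimnames = list(NULL, "all"))
  expect_equal(total_loglik(co, spec, params, delta = ones), plain,
               tolerance = 1e-12)
})

test_that("stratified likelihood with equal per-stratum parameters equals pooled", {
  cfg <- generator_config(n_patients = 250, seed = 9)
  co <- generate_cohort(cfg)
  base <- c(lambda = 0.06, k = 1.1)
  strat <- model_spec("weibull", stratification = "interval_by_donor")
  labels <- colnames(build_delta(co, "interval_by_donor"))
  p_strat <- list(baseline = stats::setNames(
    rep(list(base), length(labels)), labels))
  pooled <- total_loglik(co, model_spec("weibull"),
                         list(baseline = base))
  expect_equal(total_loglik(co, strat, p_strat), pooled,
               tolerance = 1e-12)
})

test_that("truncation term is -e^(bZ) log S(j), zero at j = 0", {
  spec <- model_spec("weibull")
  params <- list(baseline = c(lambda = 1, k = 1))
  rec <- make_record("A", 1, 2, 1, ty = 2000)
  expect_equal(truncation_term(rec, spec, params), 1)
  # j -> 0 limit (j must stay positive for the record to be valid)
  rec0 <- make_record("A", 1e-9, 2, 1, ty = 2000)
  expect_equal(truncation_term(rec0, spec, params), 1e-9,
               tolerance = 1e-6)
  # contribution depends on j only through -log S(j)
  sp <- model_spec("weibull", covariates = "acute_gvhd")
  pp <- list(baseline = c(lambda = 0.05, k = 1.3),
             beta = c(acute_gvhd = 0.4))
  r1 <- make_record("A", 35, 50, 1, ty = 2000, acute_gvhd = 1L)
  r2 <- make_record("A", 42, 50, 1, ty = 2000, acute_gvhd = 1L)
  expect_equal(individual_loglik(r1, sp, pp) - individual_loglik(r2, sp, pp),
               truncation_term(r1, sp, pp) - truncation_term(r2, sp, pp))
  # frailty case against direct marginal survival (quadrature route)
  spf <- model_spec("weibull", frailty = frailty_spec("log_normal", 0.5))
  ppf <- list(baseline = c(lambda = 0.05, k = 1.3), sigma2 = 0.5)
  fam <- hazard_family("weibull", lambda = 0.05, k = 1.3)
  rec <- make_record("A", 45, 50, 1, ty = 2000)
  expect_equal(truncation_term(rec, spf, ppf),
               -log(frailty_marginal_survival(fam,
                 frailty_spec("log_normal", 0.5), 45)),
               tolerance = 1e-8)
})

test_that("likelihood is finite on the interior for generated cohorts", {
  for (s in 1:3) {
    cfg <- generator_config(n_patients = 120, seed = 30 + s)
    co <- generate_cohort(cfg)
    spec <- model_spec("weibull", stratification = "interval_by_donor",
                       covariates = "acute_gvhd")
    params <- list(baseline = mortraj:::default_stratum_params(),
                   beta = c(acute_gvhd = 0.5))
    expect_true(is.finite(total_loglik(co, spec, params)))
  }
})
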