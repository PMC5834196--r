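# Multi-start MLE: closed-form checks, cross-validation against an
# independent fitter, delta-method algebra, determinism, diagnostics.

test_that("censored exponential sub-model matches the closed-form MLE", {
  co <- sim_cohort(800, seed = 2)
  ft <- fit_parametric(co, model_spec("weibull"), starts = quick_starts(),
                       control = quick_control(), fixed = list(k = 1))
  lam_cf <- sum(co$event_theta) /
    sum(co$exit_age_x - co$transplant_age_j)
  lam_hat <- ft$par_table$estimate[ft$par_table$par == "lambda"]
  expect_true(ft$converged)
  expect_equal(lam_hat, lam_cf, tolerance = 1e-6)
  expect_equal(ft$n_params, 1L)
})

test_that("left-truncated Weibull fit agrees with an independent implementation", {
  skip_if_not_installed("flexsurv")
  co <- sim_cohort(1500, seed = 7)
  ft <- fit_parametric(co, model_spec("weibull", covariates = "acute_gvhd"),
                       starts = quick_starts(4), control = quick_control())
  fs <- flexsurv::flexsurvreg(
    survival::Surv(transplant_age_j, exit_age_x, event_theta) ~ acute_gvhd,
    data = as.data.frame(co), dist = "weibullPH",
    inits = c(1.2, 0.05, 0.5))
  expect_equal(ft$loglik, fs$loglik, tolerance = 1e-6)
  tab <- ft$par_table
  expect_equal(tab$estimate[tab$par == "k"],
               unname(fs$res["shape", "est"]), tolerance = 1e-3)
  expect_equal(tab$estimate[tab$par == "lambda"],
               unname(fs$res["scale", "est"]), tolerance = 1e-2)
  expect_equal(tab$estimate[tab$par == "acute_gvhd"],
               unname(fs$res["acute_gvhd", "est"]), tolerance = 1e-3)
  expect_equal(tab$se[tab$par == "acute_gvhd"],
               unname(fs$res["acute_gvhd", "se"]), tolerance = 1e-2)
})

test_that("parameter recovery within 3 delta-method SEs", {
  co <- sim_cohort(3000, lambda = 0.05, k = 1.2, beta = 0.5, seed = 13)
  ft <- fit_parametric(co, model_spec("weibull", covariates = "acute_gvhd"),
                       starts = quick_starts(3), control = quick_control())
  expect_true(ft$converged)
  truth <- c("all:lambda" = 0.05, "all:k" = 1.2,
             "beta:acute_gvhd" = 0.5)
  for (nm in names(truth))
    expect_lt(z_internal(ft, nm, truth[[nm]]), 3)
})

test_that("fits are bit-identical under the same seed and dominated by larger start grids", {
  co <- sim_cohort(300, seed = 5)
  spec <- model_spec("weibull", covariates = "acute_gvhd")
  ctrl <- fit_control(sann_maxit = 25)
  f1 <- fit_parametric(co, spec, starts = start_grid(4, 77), control = ctrl)
  f2 <- fit_parametric(co, spec, starts = start_grid(4, 77), control = ctrl)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$par_table$estimate, f2$par_table$estimate)
  expect_identical(f1$best_start_index, f2$best_start_index)
  # best-of-N log-likelihood is monotone for prefix-nested grids
  f8 <- fit_parametric(co, spec, starts = start_grid(8, 77), control = ctrl)
  expect_gte(f8$loglik + 1e-9, f1$loglik)
  expect_identical(f8$start_diagnostics$negloglik[1:4],
                   f1$start_diagnostics$negloglik)
})

test_that("delta-method algebra: identity and log transforms", {
  co <- sim_cohort(600, seed = 6)
  ft <- fit_parametric(co, model_spec("gompertz"),
                       starts = quick_starts(3), control = quick_control())
  expect_true(ft$converged)
  tab <- delta_method_se(ft)
  V <- vcov(ft)
  # b is on the natural (identity) scale: se = sqrt inverse-Hessian diagonal
  bi <- which(ft$par_table$par == "b")
  expect_equal(tab$se[bi], sqrt(V[bi, bi]))
  # a is log-parametrized: se_natural = a_hat * se_log
  ai <- which(ft$par_table$par == "a")
  expect_equal(tab$se[ai], tab$estimate[ai] * sqrt(V[ai, ai]))
  # intervals contain the estimate
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
})

test_that("converged fits have a small likelihood gradient", {
  co <- sim_cohort(500, seed = 14)
  ft <- fit_parametric(co, model_spec("weibull"),
                       starts = quick_starts(), control = quick_control())
  expect_true(ft$converged)
  expect_lt(ft$grad_norm, 1e-4 * max(1, abs(ft$loglik)))
  expect_true(ft$hessian_negdef)
})

test_that("stratified fit recovers donor-specific baselines", {
  cfg <- generator_config(
    n_patients = 3000,
    stratum_params = list(related = c(lambda = 0.10, k = 1.0037),
                          unrelated = c(lambda = 0.12, k = 0.96)),
    beta_true = NULL, seed = 17)
  co <- generate_cohort(cfg)
  ft <- fit_parametric(co, model_spec("weibull", stratification = "donor"),
                       starts = quick_starts(3), control = quick_control())
  expect_true(ft$converged)
  truth <- list("related" = c(lambda = 0.10, k = 1.0037),
                "unrelated" = c(lambda = 0.12, k = 0.96))
  for (s in names(truth)) for (p in c("lambda", "k"))
    expect_lt(z_internal(ft, paste0(s, ":", p), truth[[s]][[p]]), 3)
})

test_that("frailty degeneracy detection contract", {
  co <- sim_cohort(300, seed = 19)
  ft <- fit_parametric(co, model_spec("weibull"),
                       starts = quick_starts(), control = quick_control())
  expect_error(detect_frailty_degeneracy(ft), "not a frailty fit")
})
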