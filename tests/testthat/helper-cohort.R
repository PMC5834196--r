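# Fixtures built in code: tiny hand-written cohorts and quick wrappers
# around the generator with test-scale optimizer settings.

make_record <- function(id = "P1", j = 40, x = 45, theta = 1,
                        donor = "related", ty = 2000, ...) {
  dpy <- days_per_year_default()
  df <- data.frame(id = id, transplant_age_j = j, exit_age_x = x,
                   event_theta = theta, donor_source = donor,
                   post_transplant_days = round((x - j) * dpy),
                   transplant_year = ty, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

tiny_cohort <- function() {
  as_cohort(rbind(
    make_record("P1", 35, 35.2, 1, "related", 1998, acute_gvhd = 1L),
    make_record("P2", 42, 42.5, 0, "unrelated", 2001, acute_gvhd = 0L),
    make_record("P3", 50, 58.0, 1, "unrelated", 1996, acute_gvhd = 1L),
    make_record("P4", 61, 63.0, 0, "related", 2004, acute_gvhd = 0L)))
}

# single-stratum Weibull cohort with one binary covariate effect
sim_cohort <- function(n = 1000, lambda = 0.05, k = 1.2, beta = 0.5,
                       seed = 1, censor_year = 2012, period_trend = 0,
                       frailty = frailty_spec("none")) {
  cfg <- generator_config(
    n_patients = n,
    stratum_params = list(all = c(lambda = lambda, k = k)),
    beta_true = if (is.null(beta)) NULL else c(acute_gvhd = beta),
    frailty_true = frailty, censor_year = censor_year,
    period_trend = period_trend, seed = seed)
  generate_cohort(cfg)
}

quick_starts <- function(n = 2, seed = 1) start_grid(n, seed)

# |estimate - truth| in estimation-scale standard errors: positive
# parameters are log-parametrized internally, so the comparison happens
# on the log scale, matching how the intervals are built.
z_internal <- function(fit, label, truth) {
  r <- fit$par_table[fit$par_table$label == label, ]
  stopifnot(nrow(r) == 1)
  t_int <- if (r$transform == "exp") log(truth) else truth
  abs(r$internal - t_int) / r$se_internal
}

quick_control <- function(...) fit_control(sann_maxit = 0, ...)
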