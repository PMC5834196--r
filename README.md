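# mortraj

Parametric survival modelling of age-specific mortality trajectories and
the rate of aging in transplant cohorts.

## The problem

Hematopoietic stem-cell transplantation replaces a patient's immune
system wholesale. Whether that event bends the *age-specific mortality
trajectory* — and with it the rate of aging, `d log(mu(x))/dx` — is a
question that only a parametric hazard can answer, on data with two
awkward but universal registry features: patients enter observation at
their transplant age (left truncation), and follow-up is cut at a fixed
calendar date regardless of patient state (arbitrary administrative
right-censoring). `mortraj` is for biostatisticians and demographers who
need that analysis end to end, with every stage testable against
synthetic data of the same structure.

## The model

Each patient contributes survival from transplant age `j` to exit age
`x` with death indicator `theta`, through a binary patient-by-stratum
membership matrix `delta` over post-transplant time-lapse intervals
(`t <= 100d`, `100d < t <= 365d`, `t > 365d`) crossed with donor source
(related / unrelated):

    l_i = sum_s delta_is [ theta_i (log h_s(x_i) + beta'Z_i)
                           + e^(beta'Z_i) (log S_s(x_i) - log S_s(j_i)) ]

with baseline families Gompertz `a e^(bx)`, Weibull
`lambda k x^(k-1)`, their Makeham extensions, and optional mean-1 frailty
(gamma / inverse-Gaussian / log-normal) marginalized analytically or by
Gauss–Hermite quadrature. An all-ones `delta` column collapses the model
to the conventional pooled likelihood. Estimation is multi-start maximum
likelihood (simulated-annealing exploration + BFGS polish, positive
parameters on the log scale) with delta-method standard errors from the
central-difference Hessian; model choice is AIC across families plus
forward covariate selection by likelihood-ratio test; calendar-period
(medical-improvement) effects for long-term survivors enter through
biennial event-history episode splitting. The rate of aging is `b` for
Gompertz and `(k - 1)/x` for Weibull (`k = 1` is a flat,
negligible-senescence hazard).

## Worked example

Simulate a registry-style cohort with donor-specific Weibull baselines
(shapes 1.0037 related, 0.96 unrelated — a near-flat and a decelerating
hazard) and one true covariate effect, then filter and fit:

```r
library(mortraj)

cfg <- generator_config(
  n_patients   = 4000,
  stratum_params = list(related   = c(lambda = 0.10, k = 1.0037),
                        unrelated = c(lambda = 0.12, k = 0.96)),
  beta_true    = c(acute_gvhd = 0.5),
  seed         = 42)
cohort <- generate_cohort(cfg)
flt    <- apply_eligibility_filters(cohort)   # exit age > 30, transplant age < 70

fit <- fit_parametric(flt$cohort,
         model_spec("weibull", stratification = "donor",
                    covariates = "acute_gvhd"),
         starts  = start_grid(8, 42),
         control = fit_control(sann_maxit = 25))
fit
#> <mortraj_fit> weibull, stratification = donor
#>   logLik -9138.399 on 5 free parameter(s), n = 4000; converged = TRUE
#>             label estimate       se    lower   upper
#>    related:lambda 0.060587 0.049989 0.012024 0.30528
#>         related:k 1.100100 0.170700 0.811620 1.49110
#>  unrelated:lambda 0.146780 0.080989 0.049773 0.43286
#>       unrelated:k 0.927040 0.109980 0.734710 1.16970
#>   beta:acute_gvhd 0.540170 0.036768 0.468100 0.61223
```

Every generating parameter sits inside its 95% interval: the unrelated
shape is estimated at 0.93 (truth 0.96, a decelerating inverse-J hazard),
the related shape at 1.10 (truth 1.0037, flat within its interval), and
the acute-GvHD log hazard ratio at 0.54 (truth 0.5). Downstream
quantities:

```r
rate_of_aging(hazard_family("weibull",
  lambda = fit$params_hat$baseline$unrelated[["lambda"]],
  k      = fit$params_hat$baseline$unrelated[["k"]]), 50)
#> -0.00146          # per year: the hazard declines ~0.15%/yr at age 50

aft_time_ratio(fit, "unrelated")
#> acute_gvhd
#>      0.558         # acute GvHD compresses survival time to ~56%
```

`trajectory()` tabulates hazard, log-hazard and rate-of-aging columns
over an age grid per stratum, `crossing_age()` finds where two log-hazard
lines converge, `fit_eha()` adds biennial calendar-period effects for
`t > 365`-day survivors, and `run_pipeline()` drives
simulate → filter → family selection → forward selection → EHA →
trajectories into a single run directory with a manifest. A thin
command-line wrapper lives at `inst/scripts/mortraj-cli.R`
(`simulate | fit | pipeline`).

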