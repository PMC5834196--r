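Package: mortraj
Title: Parametric Survival Models for Age-Specific Mortality Trajectories
    in Transplant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of parametric hazard models
    (Gompertz, Weibull, their Makeham extensions, and univariate frailty
    mixtures) for left-truncated, arbitrarily right-censored survival data,
    with stratum-membership (delta) matrices that keep all subjects in a
    single likelihood while assigning stratum-specific baseline hazards.
    Includes multi-start simulated-annealing optimization with quasi-Newton
    polish and delta-method inference, AIC and likelihood-ratio model
    selection with forward covariate selection, biennial event-history
    episode splitting for calendar-period effects, age-specific mortality
    trajectories and rate-of-aging curves, and a synthetic cohort generator
    emulating the structure of allogeneic stem-cell transplant registry
    follow-up data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    pracma,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    flexsurv,
    optparse
Config/testthat/edition: 3
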