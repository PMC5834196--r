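---
title: "Parametric mortality trajectories for transplant cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric mortality trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortraj)
```

## The scientific problem

Allogeneic stem-cell transplantation resets a patient's immune system, and
the question this package serves is whether — and how — that event alters
the *rate of aging*, the relative derivative of the mortality hazard
`d log(mu(x))/dx`. Answering it requires a parametric hazard (only a
parametric shape has a derivative), survival machinery that respects how
registry follow-up data actually look (entry at transplant age, follow-up
cut at a fixed calendar date), and a way to keep every patient in a single
likelihood while letting the baseline hazard differ by post-transplant
phase and donor source.

`mortraj` implements that machinery: parametric hazard families, a
stratified left-truncated right-censored likelihood, multi-start maximum
likelihood with delta-method inference, AIC/likelihood-ratio model
selection, biennial event-history adjustment for calendar-period effects,
and a synthetic registry-style cohort generator so every stage is testable
without access to confidential registry data.

## Hazard families

Ages `x` are years since birth; hazards are rates per year.

* Gompertz: `mu(x) = a e^(bx)`, the demographic default for adulthood;
  its rate of aging is the constant `b`.
* Weibull: `mu(x) = lambda k x^(k-1)`, whose rate of aging `(k-1)/x`
  decelerates with age; `k = 1` is a flat hazard (negligible senescence),
  `k < 1` a decreasing, inverse-J-tailed hazard.
* Makeham variants add an age-independent background rate `c >= 0`.

Weibull flexibility is the point: after an immunological reset the hazard
shape need not follow Gompertz, and may change with time since
transplant.

Numerical notes: the Gompertz cumulative hazard `(a/b)(e^(bx)-1)` is
computed with `expm1` and an exact `b = 0` branch; the Weibull increment
`lambda (x^k - j^k)` is computed as `lambda j^k expm1(k log(x/j))`. The
latter matters: the naive difference cancels catastrophically as
`k -> 0`, and an optimizer will happily walk into the artefactual
likelihood spike that cancellation creates. Every conditional
log-survival in the package is built from these stable increments, never
from the difference of two nearly equal log-survivals.

## The stratified likelihood

Each patient contributes their survival from transplant age `j` to exit
age `x` with event indicator `theta` (1 = died). With a binary
patient-by-stratum membership matrix `delta` (strata are the
post-transplant interval — `t <= 100` days, `100 < t <= 365` days,
`t > 365` days, right-closed — crossed with donor source), the
contribution is

```
l_i = sum_s delta_is [ theta_i (log h_s(x_i) + beta'Z_i)
                       + e^(beta'Z_i) (log S_s(x_i) - log S_s(j_i)) ]
```

Covariates act proportionally on the hazard; division by `S(j)` is the
left-truncation correction (patients must be alive to be transplanted);
`theta = 0` leaves the conditional log-survival of a censored record.
Setting `delta` to a single all-ones column collapses the model to the
conventional pooled likelihood — an identity the test-suite asserts to
machine precision, because it is the anchor for everything the delta
matrix adds. For the Weibull family the proportional-hazards coefficient
is a re-parametrization of an accelerated-failure-time effect;
`aft_time_ratio()` reports the implied survival-time ratio
`exp(-beta/k)`.

Coefficients are shared across strata by default
(`beta_sharing = "shared"`) with per-stratum baselines; `"per_stratum"`
coefficients are available where donor-source-specific adjusted estimates
are wanted. Both modes exist because either convention is defensible; the
package asserts neither as canonical.

## Frailty

An unobserved multiplicative risk `z` with mean 1 and variance `sigma2`
(the relative-risk convention) can be mixed over gamma, inverse-Gaussian
(closed Laplace transforms) or log-normal (Gauss–Hermite quadrature,
default 64 nodes, configurable) distributions. All marginal forms use the
baseline cumulative hazard from birth, so frailty selection operates from
birth onwards; `sigma2 < 1e-8` falls back to the degenerate (no-frailty)
branch to avoid cancellation in the transforms.

**Degeneracy.** On arbitrarily right-censored data the frailty variance is
often not estimable; `detect_frailty_degeneracy()` flags a fit when any of
three signals fires: the variance collapses below `1e-6`; the optimizer
cannot certify an interior optimum (gradient or curvature test fails); or
the boundary-corrected likelihood-ratio test against the no-frailty model
is non-significant (statistic below `qchisq(0.90, 1)`, the 50:50
chi-square-mixture critical value at the 5% level appropriate for a
variance pinned at the boundary of its space). The third signal is the
package's operational definition of "no measurable frailty": the first
two alone under-flag, because a maximum-likelihood variance under a true
zero lands at a small interior value in about half of all samples.

A practical identifiability warning that the simulations make vivid:
with a moderately sloped baseline, a gamma-frailty Weibull marginal is
mimicked almost perfectly by a plain Weibull with a flatter shape, so
`sigma2` is near-unidentified no matter the sample size. The variance is
well identified only when a steep individual baseline is flattened into a
population plateau — which is why the recovery simulation in the
acceptance suite uses a lifespan-scale baseline with shape 2.5 and
complete follow-up, while the degeneracy simulation uses registry-style
censored follow-up.

## Estimation

`fit_parametric()` maximizes the log-likelihood with positive parameters
(`lambda`, `k`, `a`, `c`, `sigma2`) on the log scale and `b` and all
coefficients on the natural scale. Each start runs a simulated-annealing
exploration (`optim` method SANN; iterations and temperature are
configurable, and 0 iterations skips straight to the polish) followed by
a BFGS quasi-Newton polish with a high-accuracy central-difference
gradient; the polish restarts up to twice while the gradient norm remains
above tolerance, because BFGS can stall on flat ridges such as the
Gompertz level/slope correlation. Start 1 is a deterministic
censored-exponential moment guess; the remainder are a Latin-hypercube
sample over log-parameter boxes around it, drawn from a fixed-size pool
so grids sharing a seed are prefix-nested (best-of-N log-likelihood is
then monotone in N, which the tests assert). The default grid size of
1,600 starts is a production setting; the simulations in the tests and
the acceptance script use 1–8 starts, which the well-behaved likelihoods
here reward with identical optima.

Convergence requires all of: the polish reports success, the
central-difference Hessian (internal scale, step `eps^(1/4)` per
coordinate) is negative-definite, and the gradient norm is below
`1e-4 * max(1, |loglik|)`. Ties in the best log-likelihood across starts
break to the lowest start index, so a fit is a pure function of (data,
spec, seed) — two runs with the same seed are bit-identical.

Standard errors come from the delta method on the inverse negative
Hessian: `se = estimate * se_internal` for log-parametrized quantities,
and 95% intervals are `+/-1.96` internal-scale SEs back-transformed
(asymmetric on the natural scale). A consequence worth remembering when
reading simulation checks: for a scale parameter whose relative SE is
large, "within 3 SEs of truth" is only meaningful on the estimation (log)
scale, the scale on which the intervals are actually built.

## Model selection

`aic()` is `2p - 2 logLik` with frailty variances counted in `p`;
non-converged fits are excluded from ranking (a boundary-flagged frailty
likelihood is unreliable), with the reason recorded in the
`select_family()` table. `likelihood_ratio_test()` clamps tiny negative
statistics to zero and treats anything below `-1e-6` as an optimization
failure rather than a result. `forward_select()` adds, each round, the
candidate with the smallest LRT p-value below `alpha` (default 0.05);
multi-level categorical covariates enter as whole blocks with
`df = levels - 1`; ties break by larger statistic, then name; candidates
whose fit does not converge are skipped for the round with a note, not
fatally.

Family identifiability has a sharp practical limit that the acceptance
suite documents: with entry ages on [30, 70) and follow-up
administratively cut a decade later, Weibull (`k = 1.4`) and Gompertz
hazards are observationally near-equivalent — the mean log-likelihood
margin at n = 5,000 is a fraction of a unit, and AIC picks the generating
family little better than chance. The identification experiment therefore
uses lifespan-scale mortality with complete follow-up, where hazard
curvature is expressed across a wide age span. That choice is about what
the experiment is *for* (an identification property of AIC), not about
emulating registry censoring.

## Biennial event-history analysis

For long-term survivors (`t > 365` days) the package splits follow-up
from one year post-transplant to exit at biennial calendar boundaries
(1995–96, ..., 2011–12; right-closed, so an exit exactly on a boundary
closes the earlier bin and zero-length episodes cannot arise). Calendar
position uses a mid-year transplant convention
(`transplant_year + 0.5 + elapsed`), since exact dates are absent from
the schema. Each episode is a left-truncated right-censored contribution
whose hazard is scaled by `e^(gamma_period)`; the death indicator rides
only on the terminal episode. Exposure and events are conserved exactly,
and with all period coefficients at zero the episode product telescopes
back to the unsplit likelihood — the fundamental bookkeeping identity,
asserted to `1e-10` in the acceptance suite.

Period effects are per-bin coefficients with the earliest observed bin as
reference (`"factor"`), or a single per-biennium log-linear trend
(`"linear"`). Empty bins are dropped from the design with a note. The
point of the machinery is the contrast it operationalizes: on data
generated with a 10%-per-biennium hazard decline, the EHA fit recovers
the trend, while the no-EHA fit — the same truncated data with transplant
year as a standalone covariate — mis-estimates the baseline shape far
beyond its own reported uncertainty. Transplant year as a lone covariate
captures between-patient calendar contrasts but cannot absorb the
within-patient decline, which the age-shape parameter then soaks up.

## Trajectories

`trajectory()` evaluates `mu(x) = h_s(x) e^(beta'Z)` on an age grid
(default 30–70 by 0.5 years, the eligibility window) for one stratum at a
stated covariate profile — by default the most frequent level of each
fitted covariate, with `type = "baseline"` dropping the adjustment — and
returns hazard, log-hazard and rate-of-aging columns.
`crossing_age()` locates sign changes of the log-hazard difference of two
trajectories by linear interpolation (on a semi-logarithmic plot,
proportional hazards are parallel lines, so log-scale crossings are the
meaningful notion of hazard-line convergence); identical trajectories are
reported as degenerate rather than as a crossing.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a US transplant-registry
cohort: a 30.1% related-donor share, transplant years uniform on
1995–2006, administrative censoring at the end of 2012 (mid-year
transplant convention), transplant ages from a truncated normal
(mean 45, sd 12) on [30, 69.99) — only the support is
eligibility-constrained; the shape is a package choice — and per-donor
covariate frequencies typical of such registries (acute GvHD 34–43%,
chronic GvHD 43–47%, Karnofsky >= 80 in ~82–85%, prior autologous
transplant rare for related and ~12% for unrelated grafts, five disease
groups, seven total-body-irradiation bands, nine US regions). The default
true covariate effect is a log hazard ratio of 0.5 on acute GvHD; all
other effects default to zero.

Event times are drawn by exact inverse-transform sampling on the
cumulative hazard, accumulated continuously across segment boundaries and
inverted analytically within closed-form segments
(`inverse_transform_sample()`). The default hazard is piecewise by
post-transplant interval within donor source — one coherent hazard per
patient, so a patient can traverse all three intervals — with
first-interval Weibull shapes 0.96 (unrelated) and 1.0037 (related), a
flat second interval, and a mildly rising third. The scale parameters
(0.94/1.27, 0.50/0.55, 0.039/0.050 per year) are a calibration chosen
once so that interval occupancy and death shares approximate
registry-style characteristics tables; they are documentation of the
emulation, not estimates of anything. Frailty configurations sample from
the frailty-marginal conditional law beyond the transplant age — exactly
the law the fitting routines maximize — and are restricted to
non-piecewise configurations without a period trend, where that law has a
closed or monotone-invertible form.

What the generator does *not* emulate: GvHD onset dynamics, relapse or
graft failure as separate processes, correlation between covariates,
informative censoring, or center effects. Passing tests therefore show
that the estimation machinery is correct for data satisfying the model's
assumptions; they cannot show that real registry data satisfy them.

## Problem sizes and seeds

The test-suite simulations are sized for a single CPU: parameter-recovery
fits use cohorts of 1,000–5,000 (200 replicates at n = 1,000 for interval
coverage), LRT calibration 500 replicates at n = 500, family
identification 50 replicates at n = 5,000, frailty recovery one cohort of
10,000, and the event-history contrast n = 8,000 (20 replicates for the
bias demonstration). Every stochastic step is seeded; the acceptance
script derives all its seeds from a single `--seed` argument.

## Known limitations

* Frailty variance is practically unidentifiable under flat baselines or
  heavy administrative censoring; the degeneracy detector reports this
  rather than pretending otherwise.
* Gompertz level and slope are strongly correlated on narrow age windows;
  the optimizer's restart logic handles it, but interval widths for `a`
  and `b` should be read jointly.
* Episode splitting supports shared or donor-stratified baselines only;
  interval-based stratification is meaningless within the long-term
  survivor subset.
* Covariates are fixed within an episode; continuous-time calendar
  effects (splines) are out of scope by design.
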