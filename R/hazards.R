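# Parametric hazard families and univariate frailty mixtures.
#
# All ages are in years since birth. Hazards are rates per year; cumulative
# hazards are dimensionless. Four baseline families are supported:
#
#   gompertz          mu(x) = a * exp(b * x)
#   gompertz_makeham  mu(x) = c + a * exp(b * x)
#   weibull           mu(x) = lambda * k * x^(k - 1)
#   weibull_makeham   mu(x) = c + lambda * k * x^(k - 1)
#
# A multiplicative frailty z with mean 1 and variance sigma2 can be mixed
# over gamma, inverse-Gaussian (both closed Laplace transforms) or
# log-normal (Gauss-Hermite quadrature) distributions.

#' Construct a parametric hazard family
#'
#' @param name one of `"gompertz"`, `"gompertz_makeham"`, `"weibull"`,
#'   `"weibull_makeham"`.
#' @param ... named parameters. Gompertz families take `a` (level, /yr) and
#'   `b` (log-slope, /yr); Weibull families take `lambda` (scale, /yr^k) and
#'   `k` (shape, dimensionless); Makeham variants add `c` (age-independent
#'   background rate, /yr, >= 0).
#' @return an object of class `hazard_family`
#' @examples
#' hazard_family("weibull", lambda = 0.02, k = 0.96)
#' @export
hazard_family <- function(name, ...) {
  name <- match.arg(name, c("gompertz", "gompertz_makeham",
                            "weibull", "weibull_makeham"))
  params <- list(...)
  if (length(params) == 1L && is.null(names(params)) && is.list(params[[1L]]))
    params <- params[[1L]]
  need <- family_param_names(name)
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("family '", name, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  params <- lapply(params[need], as.numeric)
  if (grepl("^weibull", name)) {
    if (params$lambda <= 0) stop("lambda must be > 0", call. = FALSE)
    if (params$k <= 0) stop("k must be > 0", call. = FALSE)
  } else {
    if (params$a <= 0) stop("a must be > 0", call. = FALSE)
  }
  if (grepl("makeham", name) && params$c < 0)
    stop("Makeham background rate c must be >= 0", call. = FALSE)
  structure(list(name = name, params = params), class = "hazard_family")
}

family_param_names <- function(name) {
  switch(name,
    gompertz = c("a", "b"),
    gompertz_makeham = c("a", "b", "c"),
    weibull = c("lambda", "k"),
    weibull_makeham = c("lambda", "k", "c"))
}

#' @export
print.hazard_family <- function(x, ...) {
  cat("<hazard_family> ", x$name, ": ",
      paste(names(x$params), signif(unlist(x$params), 6),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Frailty specification
#'
#' Univariate multiplicative frailty with mean fixed at 1 and variance
#' `sigma2` (the relative-risk convention).
#'
#' @param distribution `"none"`, `"gamma"`, `"inverse_gaussian"` or
#'   `"log_normal"`.
#' @param sigma2 frailty variance (ignored for `"none"`).
#' @param gh_nodes Gauss-Hermite node count for log-normal marginalization.
#' @return an object of class `frailty_spec`
#' @export
frailty_spec <- function(distribution = c("none", "gamma", "inverse_gaussian",
                                          "log_normal"),
                         sigma2 = 0, gh_nodes = 64L) {
  distribution <- match.arg(distribution)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  structure(list(distribution = distribution, sigma2 = sigma2,
                 gh_nodes = as.integer(gh_nodes)),
            class = "frailty_spec")
}

#' @export
print.frailty_spec <- function(x, ...) {
  if (x$distribution == "none") cat("<frailty_spec> none\n")
  else cat("<frailty_spec> ", x$distribution, ", sigma2 = ", x$sigma2,
           "\n", sep = "")
  invisible(x)
}

# sigma2 below this is treated as degenerate (no frailty) in the marginal
# forms, avoiding catastrophic cancellation in the Laplace transforms.
SIGMA2_DEGENERATE <- 1e-8

#' Hazard rate
#'
#' Instantaneous mortality rate at age `x`. When a non-degenerate `frailty`
#' is supplied the population (frailty-marginal) hazard is returned.
#'
#' @param family a [hazard_family()]
#' @param x age(s) in years
#' @param frailty optional [frailty_spec()]
#' @return rate(s) per year, same length as `x`
#' @export
hazard <- function(family, x, frailty = NULL) {
  if (has_frailty(frailty)) return(frailty_marginal_hazard(family, frailty, x))
  baseline_hazard(family, x)
}

baseline_hazard <- function(family, x) {
  p <- family$params
  switch(family$name,
    gompertz = p$a * exp(p$b * x),
    gompertz_makeham = p$c + p$a * exp(p$b * x),
    weibull = {
      check_weibull_domain(p$k, x)
      p$lambda * p$k * x^(p$k - 1)
    },
    weibull_makeham = {
      check_weibull_domain(p$k, x)
      p$c + p$lambda * p$k * x^(p$k - 1)
    })
}

check_weibull_domain <- function(k, x) {
  if (k < 1 && any(x <= 0))
    stop("Weibull hazard with k < 1 is singular at x <= 0", call. = FALSE)
  if (any(x < 0)) stop("age must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Cumulative hazard
#'
#' Integral of the hazard from 0 to `x`. The Gompertz form
#' `(a/b)(e^{bx}-1)` uses `expm1` and a `b = 0` branch so the
#' `b -> 0` limit `a*x` is reached without cancellation.
#'
#' @inheritParams hazard
#' @return dimensionless cumulative hazard(s)
#' @export
cumulative_hazard <- function(family, x, frailty = NULL) {
  if (has_frailty(frailty))
    return(-log(frailty_marginal_survival(family, frailty, x)))
  baseline_cumhaz(family, x)
}

baseline_cumhaz <- function(family, x) {
  if (any(x < 0)) stop("age must be >= 0", call. = FALSE)
  p <- family$params
  switch(family$name,
    gompertz = gompertz_cumhaz(p$a, p$b, x),
    gompertz_makeham = gompertz_cumhaz(p$a, p$b, x) + p$c * x,
    weibull = p$lambda * x^p$k,
    weibull_makeham = p$lambda * x^p$k + p$c * x)
}

gompertz_cumhaz <- function(a, b, x) {
  if (abs(b) < 1e-12) a * x else (a / b) * expm1(b * x)
}

# Lambda(x) - Lambda(j) for x > j >= 0, computed without the catastrophic
# cancellation of subtracting two nearly equal cumulative hazards (the
# x^k - j^k difference collapses numerically as k -> 0, which would let an
# optimizer walk into a spuriously unbounded likelihood).
baseline_cumhaz_diff <- function(family, x, j) {
  p <- family$params
  core <- switch(family$name,
    gompertz = ,
    gompertz_makeham = {
      if (abs(p$b) < 1e-12) p$a * (x - j)
      else (p$a / p$b) * exp(p$b * j) * expm1(p$b * (x - j))
    },
    weibull = ,
    weibull_makeham = {
      ifelse(j <= 0, p$lambda * x^p$k,
             p$lambda * j^p$k * expm1(p$k * log(x / j)))
    })
  if (grepl("makeham", family$name)) core <- core + p$c * (x - j)
  core
}

#' Survivor function
#'
#' `S(x) = exp(-cumulative hazard)`; the frailty-marginal survivor function
#' when a frailty specification is supplied.
#'
#' @inheritParams hazard
#' @return survival probability(ies)
#' @export
survivor <- function(family, x, frailty = NULL) {
  if (has_frailty(frailty)) return(frailty_marginal_survival(family, frailty, x))
  exp(-baseline_cumhaz(family, x))
}

has_frailty <- function(frailty) {
  !is.null(frailty) && frailty$distribution != "none" &&
    frailty$sigma2 > SIGMA2_DEGENERATE
}

#' Frailty-marginal survivor function
#'
#' Population survival after mixing a mean-1 frailty over the baseline
#' cumulative hazard `L = Lambda(x)`:
#' gamma, `(1 + s2 L)^(-1/s2)`; inverse-Gaussian,
#' `exp((1/s2)(1 - sqrt(1 + 2 s2 L)))`; log-normal, Gauss-Hermite
#' quadrature over `z = exp(W)`, `W ~ N(-w2/2, w2)`, `w2 = log(1 + s2)`.
#'
#' @inheritParams hazard
#' @param frailty a [frailty_spec()]
#' @export
frailty_marginal_survival <- function(family, frailty, x) {
  L <- baseline_cumhaz(family, x)
  s2 <- frailty$sigma2
  if (frailty$distribution == "none" || s2 <= SIGMA2_DEGENERATE)
    return(exp(-L))
  switch(frailty$distribution,
    gamma = (1 + s2 * L)^(-1 / s2),
    inverse_gaussian = exp((1 - sqrt(1 + 2 * s2 * L)) / s2),
    log_normal = lognormal_laplace(L, s2, frailty$gh_nodes))
}

# E[exp(-z L)] for z = exp(W), W ~ N(-w2/2, w2): mean-1 log-normal frailty.
lognormal_laplace <- function(L, s2, n_nodes) {
  w2 <- log1p(s2)
  gh <- gauss_hermite_normal(n_nodes, mu = -w2 / 2, sd = sqrt(w2))
  z <- exp(gh$x)
  out <- vapply(L, function(l) sum(gh$w * exp(-z * l)), numeric(1))
  if (any(!is.finite(out)))
    stop("log-normal frailty quadrature did not converge (non-finite result); ",
         "sigma2 = ", s2, call. = FALSE)
  out
}

# E[z exp(-z L)] / E[exp(-z L)]: expected frailty among survivors.
lognormal_mean_among_survivors <- function(L, s2, n_nodes) {
  w2 <- log1p(s2)
  gh <- gauss_hermite_normal(n_nodes, mu = -w2 / 2, sd = sqrt(w2))
  z <- exp(gh$x)
  vapply(L, function(l) {
    wz <- gh$w * exp(-z * l)
    sum(wz * z) / sum(wz)
  }, numeric(1))
}

#' Frailty-marginal hazard
#'
#' `-d/dx log` of the marginal survivor function. For gamma frailty this is
#' `h(x) / (1 + s2 Lambda(x))`; for inverse-Gaussian,
#' `h(x) (1 + 2 s2 Lambda(x))^(-1/2)`; for log-normal, `h(x)` times the
#' expected frailty among survivors (quadrature).
#'
#' @inheritParams frailty_marginal_survival
#' @export
frailty_marginal_hazard <- function(family, frailty, x) {
  h <- baseline_hazard(family, x)
  s2 <- frailty$sigma2
  if (frailty$distribution == "none" || s2 <= SIGMA2_DEGENERATE) return(h)
  L <- baseline_cumhaz(family, x)
  switch(frailty$distribution,
    gamma = h / (1 + s2 * L),
    inverse_gaussian = h / sqrt(1 + 2 * s2 * L),
    log_normal = h * lognormal_mean_among_survivors(L, s2, frailty$gh_nodes))
}

#' Rate of aging
#'
#' The relative derivative of the hazard, `d log(mu(x)) / dx`: `b` for
#' Gompertz, `(k - 1)/x` for Weibull (zero everywhere when `k = 1`, the
#' flat negligible-senescence hazard), closed forms for the Makeham
#' variants, and a central-difference derivative of the log marginal hazard
#' under frailty.
#'
#' @inheritParams hazard
#' @return rate(s) of aging per year
#' @export
rate_of_aging <- function(family, x, frailty = NULL) {
  if (any(hazard(family, x, frailty) <= 0))
    stop("rate of aging undefined where the hazard is zero", call. = FALSE)
  if (!has_frailty(frailty)) {
    p <- family$params
    return(switch(family$name,
      gompertz = rep_len(p$b, length(x)),
      weibull = (p$k - 1) / x,
      gompertz_makeham = {
        h <- p$a * exp(p$b * x)
        p$b * h / (p$c + h)
      },
      weibull_makeham = {
        h <- p$lambda * p$k * x^(p$k - 1)
        ((p$k - 1) / x) * h / (p$c + h)
      }))
  }
  vapply(x, function(xx) {
    hh <- 1e-5 * max(1, xx)
    (log(frailty_marginal_hazard(family, frailty, xx + hh)) -
       log(frailty_marginal_hazard(family, frailty, xx - hh))) / (2 * hh)
  }, numeric(1))
}
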