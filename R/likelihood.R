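# The modified stratified likelihood.
#
# Each patient i with entry (transplant) age j_i, exit age x_i and event
# indicator theta_i contributes, through the binary stratum-membership
# matrix delta,
#
#   l_i = sum_s delta_is [ theta_i (log h_s(x_i) + beta'Z_i)
#                          + e^{beta'Z_i} (log S_s(x_i) - log S_s(j_i)) ]
#
# i.e. log[ (h_s(x) e^{beta'Z})^theta * (S_s(x)/S_s(j))^{e^{beta'Z}} ]:
# covariates scale the hazard proportionally, division by S(j) handles left
# truncation at transplant, and theta = 0 leaves the conditional
# log-survival of a censored record. When the frailty specification is
# non-degenerate, h and S are the frailty-marginal forms. A single all-ones
# delta column collapses the model to the conventional unstratified
# likelihood.

STRATIFICATIONS <- c("none", "interval", "donor", "interval_by_donor")

#' Specify a survival model
#'
#' @param family baseline family name (see [hazard_family()])
#' @param frailty a [frailty_spec()]; variance is estimated when fitting
#' @param stratification `"none"`, `"interval"` (post-transplant time-lapse
#'   interval), `"donor"` (donor source) or `"interval_by_donor"` (the full
#'   3 x 2 cross)
#' @param covariates character vector of covariate column names to adjust
#'   for (multiplicatively on the hazard)
#' @param beta_sharing `"shared"` (one coefficient vector across strata,
#'   the default) or `"per_stratum"`
#' @return an object of class `model_spec`
#' @export
model_spec <- function(family = "weibull",
                       frailty = frailty_spec("none"),
                       stratification = "none",
                       covariates = character(),
                       beta_sharing = c("shared", "per_stratum")) {
  family <- match.arg(family, c("gompertz", "gompertz_makeham",
                                "weibull", "weibull_makeham"))
  stratification <- match.arg(stratification, STRATIFICATIONS)
  beta_sharing <- match.arg(beta_sharing)
  stopifnot(inherits(frailty, "frailty_spec"))
  structure(list(family = family, frailty = frailty,
                 stratification = stratification,
                 covariates = as.character(covariates),
                 beta_sharing = beta_sharing),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> family = ", x$family,
      ", frailty = ", x$frailty$distribution,
      ", stratification = ", x$stratification, "\n", sep = "")
  if (length(x$covariates))
    cat("  covariates (", x$beta_sharing, "): ",
        paste(x$covariates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

stratum_labels_for <- function(stratification) {
  switch(stratification,
    none = "all",
    interval = INTERVAL_LEVELS,
    donor = DONOR_LEVELS,
    interval_by_donor = as.vector(outer(INTERVAL_LEVELS, DONOR_LEVELS,
                                        paste, sep = ".")))
}

stratum_of <- function(cohort, stratification) {
  lab <- stratum_labels_for(stratification)
  key <- switch(stratification,
    none = rep("all", nrow(cohort)),
    interval = as.character(cohort$interval),
    donor = as.character(cohort$donor_source),
    interval_by_donor = paste(cohort$interval, cohort$donor_source,
                              sep = "."))
  if (anyNA(match(key, lab)))
    stop("record(s) with undefined stratum under '", stratification, "'",
         call. = FALSE)
  factor(key, levels = lab)
}

#' Build the binary stratum-membership (delta) matrix
#'
#' One row per patient, one column per stratum; exclusive stratification
#' gives one-hot rows, and `stratification = "none"` gives the single
#' all-ones column that reduces the model to the conventional likelihood.
#'
#' @param cohort a cohort table
#' @param stratification as in [model_spec()]
#' @return binary matrix with stratum labels as column names
#' @export
build_delta <- function(cohort, stratification = "interval_by_donor") {
  s <- stratum_of(cohort, stratification)
  lab <- levels(s)
  m <- matrix(0L, nrow(cohort), length(lab), dimnames = list(NULL, lab))
  m[cbind(seq_len(nrow(cohort)), as.integer(s))] <- 1L
  m
}

# ---- covariate design -------------------------------------------------

# Design matrix for the named covariates: binary/numeric columns enter
# as-is; character columns become treatment-coded indicator blocks with
# the alphabetically first level as reference. Returns the matrix plus a
# block map (covariate -> column indices) used by forward selection.
build_design <- function(cohort, covariates) {
  if (!length(covariates))
    return(list(Z = NULL, blocks = list(), modal = list()))
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  cols <- list()
  blocks <- list()
  modal <- list()
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.numeric(v)) {
      nu <- length(unique(v))
      # constant numeric covariates are kept (the column is still a valid
      # design column for likelihood evaluation, e.g. on single records);
      # they are only unidentified when fitted
      # centre non-binary numeric covariates (e.g. calendar year) so the
      # linear predictor stays numerically well scaled; the coefficient is
      # unchanged, the shift is absorbed by the baseline
      ctr <- if (nu > 2) mean(v) else 0
      cols[[cv]] <- matrix(v - ctr, ncol = 1, dimnames = list(NULL, cv))
      blocks[[cv]] <- cv
      tab <- sort(table(v - ctr), decreasing = TRUE)
      modal[[cv]] <- as.numeric(names(tab)[1])
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) {
        warning("covariate '", cv, "' is constant; dropped", call. = FALSE)
        next
      }
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      cols[[cv]] <- mm
      blocks[[cv]] <- colnames(mm)
      modal[[cv]] <- names(sort(table(f), decreasing = TRUE))[1]
    }
  }
  if (!length(cols)) return(list(Z = NULL, blocks = list(), modal = list()))
  list(Z = do.call(cbind, cols), blocks = blocks, modal = modal)
}

# ---- parameter template ------------------------------------------------

baseline_param_info <- function(family) {
  switch(family,
    gompertz = data.frame(par = c("a", "b"),
                          transform = c("exp", "identity")),
    gompertz_makeham = data.frame(par = c("a", "b", "c"),
                                  transform = c("exp", "identity", "exp")),
    weibull = data.frame(par = c("lambda", "k"),
                         transform = c("exp", "exp")),
    weibull_makeham = data.frame(par = c("lambda", "k", "c"),
                                 transform = c("exp", "exp", "exp")))
}

# Table describing the internal (optimizer-scale) parameter vector:
# per-stratum baselines (positive parameters on log scale), covariate
# coefficients (natural scale), then log frailty variance.
param_template <- function(spec, strata, design_cols) {
  bp <- baseline_param_info(spec$family)
  rows <- do.call(rbind, lapply(strata, function(s)
    data.frame(label = paste0(s, ":", bp$par), stratum = s, par = bp$par,
               transform = bp$transform, kind = "baseline")))
  if (!is.null(design_cols) && length(design_cols)) {
    bstrata <- if (spec$beta_sharing == "per_stratum") strata else "(shared)"
    beta_rows <- do.call(rbind, lapply(bstrata, function(s) {
      pre <- if (identical(s, "(shared)")) "beta:" else paste0(s, ":beta:")
      data.frame(label = paste0(pre, design_cols), stratum = s,
                 par = design_cols, transform = "identity", kind = "beta")
    }))
    rows <- rbind(rows, beta_rows)
  }
  if (spec$frailty$distribution != "none")
    rows <- rbind(rows, data.frame(label = "sigma2", stratum = "(shared)",
                                   par = "sigma2", transform = "exp",
                                   kind = "frailty"))
  rownames(rows) <- NULL
  rows
}

internal_to_natural <- function(internal, template) {
  ifelse(template$transform == "exp", exp(internal), internal)
}

natural_to_internal <- function(natural, template) {
  ifelse(template$transform == "exp", log(natural), natural)
}

# Structured natural-scale parameters -> internal vector in template order.
params_to_internal <- function(params, template, strata) {
  out <- numeric(nrow(template))
  for (r in seq_len(nrow(template))) {
    row <- template[r, ]
    val <- if (row$kind == "baseline") {
      b <- params$baseline
      if (!is.list(b)) b <- stats::setNames(list(b), strata[1])
      if (is.null(b[[row$stratum]]))
        stop("no baseline parameters for stratum '", row$stratum, "'",
             call. = FALSE)
      b[[row$stratum]][[row$par]]
    } else if (row$kind == "beta") {
      bt <- params$beta
      if (is.list(bt) && row$stratum != "(shared)") bt <- bt[[row$stratum]]
      v <- bt[[row$par]]
      if (is.null(v)) 0 else v
    } else params$sigma2
    if (is.null(val) || is.na(val))
      stop("missing value for parameter '", row$label, "'", call. = FALSE)
    out[r] <- val
  }
  stats::setNames(natural_to_internal(out, template), template$label)
}

internal_to_params <- function(internal, template, spec) {
  nat <- internal_to_natural(internal, template)
  strata <- unique(template$stratum[template$kind == "baseline"])
  baseline <- lapply(strata, function(s) {
    idx <- template$kind == "baseline" & template$stratum == s
    stats::setNames(nat[idx], template$par[idx])
  })
  names(baseline) <- strata
  bidx <- template$kind == "beta"
  beta <- NULL
  if (any(bidx)) {
    if (spec$beta_sharing == "per_stratum") {
      beta <- lapply(strata, function(s) {
        i <- bidx & template$stratum == s
        stats::setNames(nat[i], template$par[i])
      })
      names(beta) <- strata
    } else beta <- stats::setNames(nat[bidx], template$par[bidx])
  }
  sigma2 <- if (any(template$kind == "frailty"))
    unname(nat[template$kind == "frailty"]) else NULL
  list(baseline = baseline, beta = beta, sigma2 = sigma2)
}

# ---- likelihood data and evaluation -----------------------------------

# Assemble everything the likelihood needs from episode-level vectors.
# `extra_design` appends pre-built design columns (used for EHA period
# effects) as additional shared-coefficient blocks.
build_lldata <- function(x, j, theta, stratum, spec, cohort_covars = NULL,
                         extra_design = NULL, ids = NULL) {
  des <- build_design(cohort_covars, spec$covariates)
  Z <- des$Z
  blocks <- des$blocks
  if (!is.null(extra_design)) {
    Z <- if (is.null(Z)) extra_design else cbind(Z, extra_design)
    blocks <- c(blocks, attr(extra_design, "blocks"))
  }
  template <- param_template(spec, levels(stratum), colnames(Z))
  list(x = as.numeric(x), j = as.numeric(j), theta = as.numeric(theta),
       stratum = stratum, Z = Z, blocks = blocks, modal = des$modal,
       template = template, spec = spec,
       ids = ids %||% as.character(seq_along(x)))
}

lldata_from_cohort <- function(cohort, spec) {
  stopifnot(is_cohort(cohort), inherits(spec, "model_spec"))
  build_lldata(cohort$exit_age_x, cohort$transplant_age_j,
               cohort$event_theta, stratum_of(cohort, spec$stratification),
               spec, cohort_covars = cohort, ids = cohort$id)
}

# log h(x), log S(j), and the conditional log-survival
# logSdiff = log S(x) - log S(j) for one stratum's baseline parameters,
# marginal over frailty when non-degenerate. logSdiff is built from the
# stably computed cumulative-hazard increment over (j, x], never from the
# difference of two nearly equal log-survivals.
stratum_log_terms <- function(family, frailty, x, j) {
  s2 <- if (is.null(frailty)) 0 else frailty$sigma2
  Ld <- baseline_cumhaz_diff(family, x, j)
  Lj <- baseline_cumhaz(family, j)
  logh <- log(baseline_hazard(family, x))
  if (is.null(frailty) || frailty$distribution == "none" ||
      s2 <= SIGMA2_DEGENERATE)
    return(list(logh = logh, logSdiff = -Ld, logSj = -Lj))
  Lx <- Lj + Ld
  switch(frailty$distribution,
    gamma = list(logh = logh - log1p(s2 * Lx),
                 logSdiff = -log1p(s2 * Ld / (1 + s2 * Lj)) / s2,
                 logSj = -log1p(s2 * Lj) / s2),
    inverse_gaussian = list(
      logh = logh - 0.5 * log1p(2 * s2 * Lx),
      logSdiff = -2 * Ld / (sqrt(1 + 2 * s2 * Lx) +
                              sqrt(1 + 2 * s2 * Lj)),
      logSj = (1 - sqrt(1 + 2 * s2 * Lj)) / s2),
    log_normal = {
      lapx <- lognormal_laplace(Lx, s2, frailty$gh_nodes)
      lapj <- lognormal_laplace(Lj, s2, frailty$gh_nodes)
      small <- Ld < 1e-10 * (1 + Lj)
      diff <- log(lapx) - log(lapj)
      if (any(small))
        diff[small] <- -(lognormal_mean_among_survivors(
          Lj[small], s2, frailty$gh_nodes) * Ld[small])
      list(logh = logh + log(lognormal_mean_among_survivors(
             Lx, s2, frailty$gh_nodes)),
           logSdiff = diff, logSj = log(lapj))
    })
}

# Per-record contributions given a full internal parameter vector.
ll_contributions <- function(internal, lldata) {
  spec <- lldata$spec
  template <- lldata$template
  nat <- internal_to_natural(internal, template)
  strata <- levels(lldata$stratum)
  frailty <- NULL
  if (spec$frailty$distribution != "none") {
    frailty <- spec$frailty
    frailty$sigma2 <- unname(nat[template$kind == "frailty"])
  }
  out <- numeric(length(lldata$x))
  for (si in seq_along(strata)) {
    s <- strata[si]
    idx <- which(as.integer(lldata$stratum) == si)
    if (!length(idx)) next
    bi <- template$kind == "baseline" & template$stratum == s
    fam <- hazard_family(spec$family,
                         stats::setNames(as.list(nat[bi]), template$par[bi]))
    eta <- 0
    if (!is.null(lldata$Z)) {
      bsel <- template$kind == "beta" &
        template$stratum == (if (spec$beta_sharing == "per_stratum") s
                             else "(shared)")
      beta <- nat[bsel]
      eta <- drop(lldata$Z[idx, , drop = FALSE] %*% beta)
    }
    lt <- stratum_log_terms(fam, frailty, lldata$x[idx], lldata$j[idx])
    out[idx] <- lldata$theta[idx] * (lt$logh + eta) +
      exp(eta) * lt$logSdiff
  }
  out
}

#' Total log-likelihood of a cohort under a model
#'
#' Sum of per-patient left-truncated, right-censored contributions. When a
#' `delta` matrix is supplied explicitly, the general weighted form
#' `sum_i sum_s delta_is l_is` is evaluated; by default the exclusive
#' one-hot matrix implied by the spec's stratification is used (a single
#' all-ones column under `stratification = "none"`, the conventional
#' pooled likelihood).
#'
#' @param cohort a cohort table
#' @param spec a [model_spec()]
#' @param params natural-scale parameters: a list with `baseline` (named
#'   vector for one stratum, or a list of named vectors keyed by stratum
#'   label), optional `beta` (named by design column), optional `sigma2`
#' @param delta optional binary matrix, rows = patients, columns = strata
#'   labelled as in the spec's stratification
#' @return log-likelihood value
#' @export
total_loglik <- function(cohort, spec, params, delta = NULL) {
  lldata <- lldata_from_cohort(cohort, spec)
  internal <- params_to_internal(params, lldata$template,
                                 levels(lldata$stratum))
  if (is.null(delta)) {
    val <- sum(ll_contributions(internal, lldata))
  } else {
    strata <- levels(lldata$stratum)
    if (!identical(colnames(delta), strata))
      stop("delta columns must match stratum labels: ",
           paste(strata, collapse = ", "), call. = FALSE)
    M <- sapply(seq_along(strata), function(si) {
      ld <- lldata
      ld$stratum <- factor(rep(strata[si], length(ld$x)), levels = strata)
      ll_contributions(internal, ld)
    })
    val <- sum(delta * M)
  }
  if (!is.finite(val))
    stop("non-finite log-likelihood; offending record(s): ",
         paste(utils::head(lldata$ids[!is.finite(
       ll_contributions(internal, lldata))], 5), collapse = ", "),
         call. = FALSE)
  val
}

#' Log-likelihood contribution of a single patient record
#'
#' @param record a one-row cohort table (or a list/data.frame coercible by
#'   [as_cohort()])
#' @inheritParams total_loglik
#' @param delta_row optional binary vector over strata overriding the
#'   record's own stratum membership
#' @export
individual_loglik <- function(record, spec, params, delta_row = NULL) {
  cohort <- if (is_cohort(record)) record else as_cohort(as.data.frame(record))
  stopifnot(nrow(cohort) == 1L)
  delta <- if (is.null(delta_row)) NULL else
    matrix(delta_row, nrow = 1,
           dimnames = list(NULL, stratum_labels_for(spec$stratification)))
  total_loglik(cohort, spec, params, delta = delta)
}

#' Left-truncation term of a record
#'
#' The additive log-likelihood correction for conditioning on survival to
#' the recruitment (transplant) age `j`: `-e^{beta'Z} log S(j)`, i.e. the
#' log of the reciprocal survivor function at entry, scaled by the
#' record's covariate effect. Zero when `j = 0`.
#'
#' @inheritParams individual_loglik
#' @export
truncation_term <- function(record, spec, params) {
  cohort <- if (is_cohort(record)) record else as_cohort(as.data.frame(record))
  stopifnot(nrow(cohort) == 1L)
  lldata <- lldata_from_cohort(cohort, spec)
  internal <- params_to_internal(params, lldata$template,
                                 levels(lldata$stratum))
  template <- lldata$template
  nat <- internal_to_natural(internal, template)
  s <- as.character(lldata$stratum[1])
  bi <- template$kind == "baseline" & template$stratum == s
  fam <- hazard_family(spec$family,
                       stats::setNames(as.list(nat[bi]), template$par[bi]))
  frailty <- NULL
  if (spec$frailty$distribution != "none") {
    frailty <- spec$frailty
    frailty$sigma2 <- unname(nat[template$kind == "frailty"])
  }
  eta <- 0
  if (!is.null(lldata$Z)) {
    bsel <- template$kind == "beta" &
      template$stratum == (if (spec$beta_sharing == "per_stratum") s
                           else "(shared)")
    eta <- drop(lldata$Z[1, , drop = FALSE] %*% nat[bsel])
  }
  lt <- stratum_log_terms(fam, frailty, lldata$x[1], lldata$j[1])
  if (!is.finite(lt$logSj))
    stop("survival at truncation age underflowed to zero (impossible ",
         "truncation) for record ", lldata$ids[1], call. = FALSE)
  -exp(eta) * lt$logSj
}
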