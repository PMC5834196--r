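# Biennial event-history analysis (EHA) for long-term survivors.
#
# Each t>365-day survivor's follow-up from one year post-transplant to exit
# is split into episodes at biennial calendar boundaries. Every episode is
# a left-truncated (at its entry age), right-censored likelihood
# contribution whose hazard is scaled by e^(gamma_period), so
# calendar-period (medical-improvement) effects are estimated jointly with
# the age-based baseline. With all period coefficients at zero the episode
# product telescopes back to the unsplit likelihood, which is the
# fundamental bookkeeping identity of the splitting.
#
# Calendar position is computed with a mid-year transplant convention:
# calendar time at elapsed time t is transplant_year + 0.5 + t.

biennial_edges <- function(calendar_start, calendar_end) {
  n_bins <- ceiling((calendar_end + 1 - calendar_start) / 2)
  calendar_start + 2 * (0:n_bins)
}

biennial_labels <- function(calendar_start, calendar_end) {
  e <- biennial_edges(calendar_start, calendar_end)
  sprintf("%d-%02d", e[-length(e)], (e[-length(e)] + 1) %% 100)
}

#' Split long-term survivors into biennial calendar episodes
#'
#' Operates on the `t > 365-day` (interval `I3`) subset. Follow-up from
#' `min_post_days` after transplant to exit is partitioned at biennial
#' calendar boundaries (bins 1995-96, ..., 2011-12, right-closed, so an
#' exit exactly on a boundary closes the earlier bin and no zero-length
#' episode arises). The death indicator is carried only by the terminal
#' episode; exposure and events are conserved exactly. Follow-up outside
#' the calendar window is clipped with a warning.
#'
#' @param cohort a cohort table (only its `I3` records are split)
#' @param calendar_start,calendar_end calendar window (defaults 1995-2012)
#' @param min_post_days start of the long-term-survivor window in days
#'   after transplant (default 365)
#' @return an `episode_table` data.frame: `patient_id`, `period` (factor
#'   over all bins), `entry_age`, `exit_age`, `event`, `donor_source`,
#'   `transplant_year`, plus the cohort's covariate columns
#' @export
split_biennial <- function(cohort, calendar_start = 1995,
                           calendar_end = 2012, min_post_days = 365) {
  stopifnot(is_cohort(cohort))
  dpy <- attr(cohort, "days_per_year") %||% days_per_year_default()
  i3 <- cohort[cohort$interval == "I3", , drop = FALSE]
  if (!nrow(i3)) stop("no t>365-day (I3) records to split", call. = FALSE)
  t0 <- min_post_days / dpy
  lo <- calendar_start
  hi <- calendar_end + 1  # right edge of the last biennial bin
  labels <- biennial_labels(calendar_start, calendar_end)
  covs <- cohort_covariates(i3)

  cal_entry <- i3$transplant_year + 0.5 + t0
  cal_exit <- i3$transplant_year + 0.5 + (i3$exit_age_x - i3$transplant_age_j)
  clipped <- cal_entry < lo | cal_exit > hi
  if (any(clipped))
    warning(sum(clipped), " record(s) clipped to the ", calendar_start, "-",
            calendar_end, " calendar window", call. = FALSE)
  theta <- i3$event_theta
  theta[cal_exit > hi] <- 0  # death beyond the window is not observed in it
  cal_entry <- pmax(cal_entry, lo)
  cal_exit <- pmin(cal_exit, hi)
  keep <- cal_exit > cal_entry
  out <- vector("list", nrow(i3))
  for (r in which(keep)) {
    edges <- biennial_edges(calendar_start, calendar_end)
    cuts <- sort(unique(c(cal_entry[r],
                          edges[edges > cal_entry[r] & edges < cal_exit[r]],
                          cal_exit[r])))
    ne <- length(cuts) - 1L
    mid <- (cuts[-1] + cuts[-(ne + 1)]) / 2
    bin <- floor((mid - lo) / 2) + 1L
    offset <- i3$transplant_age_j[r] - (i3$transplant_year[r] + 0.5)
    ep <- data.frame(
      patient_id = i3$id[r],
      period = labels[bin],
      entry_age = offset + cuts[-(ne + 1)],
      exit_age = offset + cuts[-1],
      event = c(rep(0, ne - 1L), theta[r]),
      donor_source = i3$donor_source[r],
      transplant_year = i3$transplant_year[r],
      stringsAsFactors = FALSE)
    for (cv in covs) ep[[cv]] <- i3[[cv]][r]
    out[[r]] <- ep
  }
  ep <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(ep) <- NULL
  ep$period <- factor(ep$period, levels = labels)
  attr(ep, "calendar_start") <- calendar_start
  attr(ep, "calendar_end") <- calendar_end
  attr(ep, "min_post_days") <- min_post_days
  attr(ep, "days_per_year") <- dpy
  class(ep) <- c("episode_table", "data.frame")
  ep
}

episode_period_design <- function(episodes, period_effect) {
  obs <- levels(droplevels(episodes$period))
  ref <- obs[1]
  if (period_effect == "linear") {
    all_lv <- levels(episodes$period)
    idx <- match(as.character(episodes$period), all_lv)
    X <- matrix(idx - match(ref, all_lv), ncol = 1,
                dimnames = list(NULL, "period_trend"))
    attr(X, "blocks") <- list(period = "period_trend")
  } else {
    others <- obs[-1]
    X <- sapply(others, function(lv) as.numeric(episodes$period == lv))
    X <- matrix(X, nrow = nrow(episodes),
                dimnames = list(NULL, paste0("period_", others)))
    attr(X, "blocks") <- list(period = colnames(X))
  }
  attr(X, "reference") <- ref
  attr(X, "observed") <- obs
  X
}

episode_lldata <- function(episodes, spec, period_effect = "factor",
                           with_period = TRUE) {
  if (!spec$stratification %in% c("none", "donor"))
    stop("EHA supports stratification 'none' or 'donor' only", call. = FALSE)
  stratum <- if (spec$stratification == "donor")
    factor(episodes$donor_source, levels = DONOR_LEVELS)
  else factor(rep("all", nrow(episodes)), levels = "all")
  dropped <- setdiff(levels(episodes$period),
                     levels(droplevels(episodes$period)))
  if (length(dropped) && with_period)
    message("empty biennial bin(s) dropped from the design: ",
            paste(dropped, collapse = ", "))
  X <- if (with_period) episode_period_design(episodes, period_effect)
       else NULL
  build_lldata(episodes$exit_age, episodes$entry_age, episodes$event,
               stratum, spec, cohort_covars = episodes, extra_design = X,
               ids = paste0(episodes$patient_id, "/", episodes$period))
}

#' Episode-level log-likelihood at given parameters
#'
#' Evaluates the EHA likelihood of an episode table at natural-scale
#' parameters; `period_coefs` is a named vector of per-bin log hazard
#' ratios (missing bins, including the reference, count as zero). With all
#' period coefficients zero this equals the unsplit likelihood of the same
#' follow-up (left-truncated at the episode window start).
#'
#' @param episodes an `episode_table` from [split_biennial()]
#' @param spec a [model_spec()] (stratification `"none"` or `"donor"`)
#' @param params natural-scale parameters as in [total_loglik()]
#' @param period_coefs optional named numeric vector of period effects,
#'   names matching the bin labels
#' @export
episode_loglik <- function(episodes, spec, params, period_coefs = NULL) {
  with_period <- !is.null(period_coefs) && length(period_coefs) > 0
  lldata <- suppressMessages(
    episode_lldata(episodes, spec, period_effect = "factor",
                   with_period = with_period))
  if (with_period) {
    pcols <- grep("^period_", lldata$template$par[lldata$template$kind ==
                                                    "beta"], value = TRUE)
    beta <- params$beta %||% numeric(0)
    for (pc in pcols) {
      lv <- sub("^period_", "", pc)
      beta[pc] <- if (lv %in% names(period_coefs)) period_coefs[[lv]] else 0
    }
    params$beta <- beta
  }
  internal <- params_to_internal(params, lldata$template,
                                 levels(lldata$stratum))
  sum(ll_contributions(internal, lldata))
}

#' Fit the biennial event-history model
#'
#' Splits the `I3` subset into biennial episodes and maximizes the
#' episode likelihood with the hazard scaled by `e^(gamma_period)`.
#' `period_effect = "factor"` estimates one coefficient per observed bin
#' (the earliest observed bin is the reference, fixed at zero);
#' `"linear"` estimates a single log-linear trend per biennium.
#'
#' @inheritParams split_biennial
#' @param spec a [model_spec()] (stratification `"none"` or `"donor"`)
#' @param starts,control,fixed as in [fit_parametric()]; `fixed =
#'   list(period = 0)` pins every period effect at zero, reproducing the
#'   unsplit fit
#' @param period_effect `"factor"` or `"linear"`
#' @return a `mortraj_fit` (subclass `mortraj_eha_fit`) whose period
#'   coefficients are recovered by [period_effects()]
#' @export
fit_eha <- function(cohort, spec, starts = start_grid(),
                    control = fit_control(),
                    period_effect = c("factor", "linear"),
                    calendar_start = 1995, calendar_end = 2012,
                    min_post_days = 365, fixed = NULL) {
  period_effect <- match.arg(period_effect)
  episodes <- split_biennial(cohort, calendar_start, calendar_end,
                             min_post_days)
  lldata <- episode_lldata(episodes, spec, period_effect)
  fit <- fit_engine(lldata, starts = starts, control = control,
                    fixed = fixed)
  fit$episodes <- episodes
  fit$period_effect <- period_effect
  fit$period_reference <- attr(
    episode_period_design(episodes, period_effect), "reference")
  class(fit) <- c("mortraj_eha_fit", class(fit))
  fit
}

#' Extract calendar-period effects from an EHA fit
#'
#' @param fit a `mortraj_eha_fit`
#' @return for a factor fit, a named vector of per-bin log hazard ratios
#'   including the reference bin at 0; for a linear fit, the per-biennium
#'   trend coefficient
#' @export
period_effects <- function(fit) {
  stopifnot(inherits(fit, "mortraj_eha_fit"))
  tab <- fit$par_table
  pe <- tab[tab$kind == "beta" & grepl("^period_", tab$par), , drop = FALSE]
  if (fit$period_effect == "linear")
    return(stats::setNames(pe$estimate, "per_biennium_trend"))
  out <- stats::setNames(pe$estimate, sub("^period_", "", pe$par))
  c(stats::setNames(0, fit$period_reference), out)
}
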