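# Age-specific mortality trajectories and rate-of-aging curves from a
# fitted model, plus hazard-line crossing detection on the log scale
# (semi-logarithmic plots turn proportional hazards into parallel lines,
# so a crossing of log-hazards is the meaningful notion of convergence).

#' Age-specific mortality trajectory of a fitted stratum
#'
#' Evaluates `mu(x) = h_s(x) e^(beta'Z)` over an age grid for one stratum
#' of a fit, at a stated covariate profile. The default profile is the
#' most frequent level of each fitted covariate in the fitting cohort;
#' `type = "baseline"` drops the covariate adjustment entirely.
#'
#' @param fit a `mortraj_fit`
#' @param stratum stratum label (defaults to the only stratum)
#' @param covariate_profile named list of covariate values overriding the
#'   modal profile
#' @param ages age grid in years (default 30-70 by 0.5, the eligibility
#'   window)
#' @param type `"adjusted"` (profile-scaled) or `"baseline"`
#' @return a `trajectory_table` data.frame with columns `age`, `hazard`,
#'   `log_hazard`, `rate_of_aging`
#' @export
trajectory <- function(fit, stratum = NULL, covariate_profile = list(),
                       ages = seq(30, 70, by = 0.5),
                       type = c("adjusted", "baseline")) {
  stopifnot(inherits(fit, "mortraj_fit"))
  type <- match.arg(type)
  if (is.null(stratum)) {
    if (length(fit$strata) > 1)
      stop("fit has strata ", paste(fit$strata, collapse = ", "),
           "; specify one", call. = FALSE)
    stratum <- fit$strata
  }
  if (!stratum %in% fit$strata)
    stop("stratum '", stratum, "' not in fit (",
         paste(fit$strata, collapse = ", "), ")", call. = FALSE)
  tab <- fit$par_table
  bi <- tab$kind == "baseline" & tab$stratum == stratum
  fam <- hazard_family(fit$spec$family,
                       stats::setNames(as.list(tab$estimate[bi]),
                                       tab$par[bi]))
  frailty <- NULL
  if (fit$spec$frailty$distribution != "none") {
    frailty <- fit$spec$frailty
    frailty$sigma2 <- fit$sigma2_hat
  }
  eta <- if (type == "baseline") 0
         else profile_eta(fit, stratum, covariate_profile)
  h <- hazard(fam, ages, frailty) * exp(eta)
  structure(data.frame(age = ages, hazard = h, log_hazard = log(h),
                       rate_of_aging = rate_of_aging(fam, ages, frailty)),
            stratum = stratum, eta = eta, type = type,
            class = c("trajectory_table", "data.frame"))
}

# Linear predictor of a covariate profile: modal levels of the fitting
# cohort, overridden by user-specified values.
profile_eta <- function(fit, stratum, covariate_profile) {
  tab <- fit$par_table
  bsel <- tab$kind == "beta" & !grepl("^period", tab$par) &
    tab$stratum == (if (fit$spec$beta_sharing == "per_stratum") stratum
                    else "(shared)")
  if (!any(bsel)) return(0)
  profile <- utils::modifyList(fit$modal_profile,
                               covariate_profile[names(covariate_profile) %in%
                                                   names(fit$blocks)])
  bad <- setdiff(names(covariate_profile), names(fit$blocks))
  if (length(bad))
    stop("profile names not in the fitted model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  eta <- 0
  for (cv in names(fit$blocks)) {
    if (!cv %in% names(profile)) next
    val <- profile[[cv]]
    for (col in fit$blocks[[cv]]) {
      b <- tab$estimate[bsel & tab$par == col]
      if (!length(b)) next
      z <- if (is.numeric(val)) val else as.numeric(paste0(cv, val) == col)
      eta <- eta + b * z
    }
  }
  eta
}

#' Ages at which two log-hazard trajectories cross
#'
#' Finds every age where the difference of log-hazards changes sign,
#' linearly interpolating between grid points. Identical trajectories are
#' degenerate (difference identically zero) and return no crossing, with
#' attribute `degenerate = TRUE`.
#'
#' @param traj_a,traj_b `trajectory_table`s on the same age grid
#' @param tol absolute tolerance for treating the difference as zero
#' @return numeric vector of crossing ages (possibly empty), ordered
#' @export
crossing_age <- function(traj_a, traj_b, tol = 1e-12) {
  stopifnot(inherits(traj_a, "trajectory_table"),
            inherits(traj_b, "trajectory_table"))
  if (!isTRUE(all.equal(traj_a$age, traj_b$age)))
    stop("trajectories are not on the same age grid", call. = FALSE)
  d <- traj_a$log_hazard - traj_b$log_hazard
  if (all(abs(d) <= tol))
    return(structure(numeric(0), degenerate = TRUE))
  s <- sign(d)
  out <- numeric(0)
  for (i in seq_len(length(d) - 1)) {
    if (s[i] == 0) { out <- c(out, traj_a$age[i]); next }
    if (s[i + 1] != 0 && s[i] != s[i + 1]) {
      a0 <- traj_a$age[i]; a1 <- traj_a$age[i + 1]
      out <- c(out, a0 + (a1 - a0) * d[i] / (d[i] - d[i + 1]))
    }
  }
  if (s[length(d)] == 0) out <- c(out, traj_a$age[length(d)])
  structure(sort(unique(out)), degenerate = FALSE)
}

#' Write a trajectory table to CSV
#' @param traj a `trajectory_table`
#' @param path file path
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Plot trajectories on a semi-logarithmic axis
#'
#' Base-graphics rendering of one or more trajectories with the hazard on
#' a log-scaled y axis.
#'
#' @param trajs a named list of `trajectory_table`s
#' @param main plot title
#' @param ... passed to [graphics::matplot()]
#' @export
plot_trajectories <- function(trajs, main = "Age-specific mortality", ...) {
  if (inherits(trajs, "trajectory_table")) trajs <- list(trajs)
  ages <- trajs[[1]]$age
  H <- sapply(trajs, function(t) t$hazard)
  graphics::matplot(ages, H, type = "l", log = "y", xlab = "age (years)",
                    ylab = "hazard (/yr)", main = main, lty = seq_along(trajs),
                    col = 1, ...)
  if (!is.null(names(trajs)))
    graphics::legend("topright", legend = names(trajs),
                     lty = seq_along(trajs), bty = "n")
  invisible(NULL)
}
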