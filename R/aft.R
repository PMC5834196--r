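# The Weibull proportional-hazards fit is a re-parametrization of an
# accelerated-failure-time model: a hazard ratio e^beta corresponds to a
# survival-time ratio exp(-beta/k).

#' AFT time ratios of a Weibull fit
#'
#' Converts covariate log hazard ratios into accelerated-failure-time
#' survival-time ratios `exp(-beta/k)` using the shape of the requested
#' stratum.
#'
#' @param fit a `mortraj_fit` of a Weibull-family model
#' @param stratum stratum whose shape to use (default: the only one)
#' @return named vector of time ratios per design column
#' @export
aft_time_ratio <- function(fit, stratum = NULL) {
  stopifnot(inherits(fit, "mortraj_fit"))
  if (!grepl("^weibull", fit$spec$family))
    stop("AFT time ratios are defined for Weibull-family fits", call. = FALSE)
  if (is.null(stratum)) {
    if (length(fit$strata) > 1)
      stop("specify a stratum", call. = FALSE)
    stratum <- fit$strata
  }
  tab <- fit$par_table
  k <- tab$estimate[tab$kind == "baseline" & tab$stratum == stratum &
                      tab$par == "k"]
  bsel <- tab$kind == "beta" & !grepl("^period", tab$par) &
    tab$stratum == (if (fit$spec$beta_sharing == "per_stratum") stratum
                    else "(shared)")
  stats::setNames(exp(-tab$estimate[bsel] / k), tab$par[bsel])
}
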