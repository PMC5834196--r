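# Model selection: AIC over baseline families (with or without frailty),
# likelihood-ratio tests for nested models, and greedy forward selection
# of covariates at a fixed significance level.

#' Akaike information criterion of a fit
#'
#' `2 * n_params - 2 * loglik`. Frailty variances count as parameters.
#' Non-converged fits carry an unreliable likelihood, so their AIC is
#' returned as `NA` with a warning.
#'
#' @param fit a `mortraj_fit`
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "mortraj_fit"))
  if (!isTRUE(fit$converged)) {
    warning("AIC of a non-converged fit is unreliable; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  2 * fit$n_params - 2 * fit$loglik
}

#' Likelihood-ratio test for nested fits
#'
#' @param nested fit of the restricted model
#' @param full fit of the enclosing model (same data)
#' @return list with `statistic` (`2 * (loglik_full - loglik_nested)`,
#'   small negatives clamped to zero), `df` (difference in free
#'   parameters), and `p_value` (chi-square upper tail)
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "mortraj_fit"), inherits(full, "mortraj_fit"))
  if (nested$n_obs != full$n_obs)
    stop("fits are not on the same data (n differs)", call. = FALSE)
  df <- full$n_params - nested$n_params
  if (df < 0) stop("'full' must not have fewer free parameters than ",
                   "'nested'", call. = FALSE)
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6)
    stop("negative LRT statistic (", format(stat),
         "): the full model failed to reach the nested optimum; ",
         "increase the number of starts", call. = FALSE)
  stat <- max(stat, 0)
  if (df == 0) {
    if (stat > 1e-6)
      stop("models have equal dimension but different likelihoods; ",
           "they are not nested", call. = FALSE)
    return(structure(list(statistic = 0, df = 0L, p_value = 1),
                     class = "mortraj_lrt"))
  }
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "mortraj_lrt")
}

#' @export
print.mortraj_lrt <- function(x, ...) {
  cat("LRT: statistic = ", format(x$statistic), ", df = ", x$df,
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Rank baseline families (optionally with frailty) by AIC
#'
#' Fits each candidate family/frailty combination with a common
#' stratification and covariate set and ranks converged, non-degenerate
#' fits by AIC. Frailty fits flagged at the variance boundary are excluded
#' from the ranking (their likelihood is unreliable), with the reason
#' recorded.
#'
#' @param cohort a cohort table
#' @param families character vector of family names
#' @param frailties character vector of frailty distribution names
#'   (crossed with families)
#' @param spec template [model_spec()] supplying stratification/covariates
#' @param starts,control forwarded to [fit_parametric()]
#' @return list with `table` (family, frailty, loglik, n_params, aic,
#'   converged, excluded, reason, rank), `chosen` (the winning
#'   `model_spec`) and `fits`
#' @export
select_family <- function(cohort,
                          families = c("gompertz", "gompertz_makeham",
                                       "weibull", "weibull_makeham"),
                          frailties = "none",
                          spec = model_spec(),
                          starts = start_grid(), control = fit_control()) {
  grid <- expand.grid(family = families, frailty = frailties,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- spec
    sp$family <- grid$family[i]
    sp$frailty <- frailty_spec(grid$frailty[i],
                               sigma2 = if (grid$frailty[i] == "none") 0
                                        else 0.25)
    ft <- tryCatch(fit_parametric(cohort, sp, starts = starts,
                                  control = control),
                   error = function(e) NULL)
    fits[[i]] <- ft
    excluded <- FALSE; reason <- ""
    if (is.null(ft)) { excluded <- TRUE; reason <- "fit error" }
    else if (!isTRUE(ft$converged)) { excluded <- TRUE
      reason <- "non-convergence" }
    else if (isTRUE(ft$frailty_boundary_flag)) { excluded <- TRUE
      reason <- "frailty variance at boundary" }
    rows[[i]] <- data.frame(
      family = grid$family[i], frailty = grid$frailty[i],
      loglik = if (is.null(ft)) NA_real_ else ft$loglik,
      n_params = if (is.null(ft)) NA_integer_ else ft$n_params,
      aic = if (excluded) NA_real_ else 2 * ft$n_params - 2 * ft$loglik,
      converged = !is.null(ft) && isTRUE(ft$converged),
      excluded = excluded, reason = reason)
  }
  tab <- do.call(rbind, rows)
  tab$rank <- NA_integer_
  ok <- which(!tab$excluded)
  tab$rank[ok] <- rank(tab$aic[ok], ties.method = "first")
  chosen <- NULL
  if (length(ok)) {
    w <- ok[which.min(tab$aic[ok])]
    chosen <- spec
    chosen$family <- tab$family[w]
    chosen$frailty <- frailty_spec(tab$frailty[w],
                                   sigma2 = if (tab$frailty[w] == "none") 0
                                            else 0.25)
  }
  structure(list(table = tab, chosen = chosen, fits = fits),
            class = "family_selection")
}

#' @export
print.family_selection <- function(x, ...) {
  tab <- x$table
  tab$loglik <- signif(tab$loglik, 7)
  tab$aic <- signif(tab$aic, 7)
  print(tab[order(tab$excluded, tab$rank), ], row.names = FALSE)
  invisible(x)
}

#' Forward selection of covariates by likelihood-ratio test
#'
#' Greedy loop: at each round every remaining candidate is added to the
#' current model and tested against it; the candidate with the smallest
#' LRT p-value is accepted if `p < alpha`, otherwise selection stops.
#' Multi-level categorical covariates enter as whole blocks
#' (df = levels - 1). Ties in p are broken by the larger statistic, then
#' lexicographic name. Candidates whose fit fails to converge are skipped
#' for that round with a logged reason.
#'
#' @param cohort a cohort table
#' @param base_spec [model_spec()] of the starting model (its covariates
#'   are always retained)
#' @param candidates character vector of candidate covariate names
#' @param alpha significance level for entry (default 0.05)
#' @param starts,control forwarded to [fit_parametric()]
#' @return list with `spec` (final model), `fit` (its fit), `trail`
#'   (data.frame: round, covariate, statistic, df, p_value, accepted,
#'   note) and `base_fit`
#' @export
forward_select <- function(cohort, base_spec, candidates, alpha = 0.05,
                           starts = start_grid(), control = fit_control()) {
  stopifnot(inherits(base_spec, "model_spec"))
  current <- base_spec
  current_fit <- fit_parametric(cohort, current, starts = starts,
                                control = control)
  base_fit <- current_fit
  remaining <- setdiff(candidates, base_spec$covariates)
  trail <- list()
  round <- 0L
  while (length(remaining) && alpha > 0) {
    round <- round + 1L
    rows <- list()
    fits <- list()
    for (cv in remaining) {
      sp <- current
      sp$covariates <- c(current$covariates, cv)
      ft <- tryCatch(fit_parametric(cohort, sp, starts = starts,
                                    control = control),
                     error = function(e) NULL)
      if (is.null(ft) || !isTRUE(ft$converged)) {
        rows[[cv]] <- data.frame(round = round, covariate = cv,
                                 statistic = NA_real_, df = NA_integer_,
                                 p_value = NA_real_, accepted = FALSE,
                                 note = "skipped: non-convergence")
        next
      }
      lrt <- likelihood_ratio_test(current_fit, ft)
      fits[[cv]] <- ft
      rows[[cv]] <- data.frame(round = round, covariate = cv,
                               statistic = lrt$statistic, df = lrt$df,
                               p_value = lrt$p_value, accepted = FALSE,
                               note = "")
    }
    rt <- do.call(rbind, rows)
    ok <- rt[!is.na(rt$p_value), , drop = FALSE]
    if (nrow(ok)) {
      ord <- order(ok$p_value, -ok$statistic, ok$covariate)
      winner <- ok$covariate[ord[1]]
      if (ok$p_value[ord[1]] < alpha) {
        rt$accepted[rt$covariate == winner] <- TRUE
        current$covariates <- c(current$covariates, winner)
        current_fit <- fits[[winner]]
        remaining <- setdiff(remaining, winner)
        trail[[round]] <- rt
        next
      }
    }
    trail[[round]] <- rt
    break
  }
  trail <- if (length(trail)) do.call(rbind, trail) else
    data.frame(round = integer(), covariate = character(),
               statistic = numeric(), df = integer(), p_value = numeric(),
               accepted = logical(), note = character())
  rownames(trail) <- NULL
  structure(list(spec = current, fit = current_fit, trail = trail,
                 base_fit = base_fit, alpha = alpha),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("Forward selection (alpha = ", x$alpha, "): selected ",
      if (length(x$spec$covariates))
        paste(x$spec$covariates, collapse = ", ") else "(none)",
      "\n", sep = "")
  if (nrow(x$trail)) {
    tr <- x$trail
    tr$statistic <- signif(tr$statistic, 5)
    tr$p_value <- signif(tr$p_value, 4)
    print(tr, row.names = FALSE)
  }
  invisible(x)
}
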