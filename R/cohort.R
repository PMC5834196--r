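# Patient-level data model: cohort tables, eligibility filtering,
# post-transplant interval categorization, and delimited-text I/O.
#
# A cohort is a data.frame with one row per patient and the core columns
#   id, transplant_age_j, exit_age_x, event_theta, donor_source,
#   post_transplant_days, transplant_year
# plus any of the recognized covariate columns. Ages are continuous years;
# post-transplant durations are stored in days and converted with a
# configurable days-per-year constant (default 365.25).

CORE_COLUMNS <- c("id", "transplant_age_j", "exit_age_x", "event_theta",
                  "donor_source", "post_transplant_days", "transplant_year")

COVARIATE_NAMES <- c("acute_gvhd", "chronic_gvhd", "disease", "conditioning",
                     "tbi_band", "graft_type", "karnofsky_ge80", "prior_auto",
                     "sex", "region")

DONOR_LEVELS <- c("related", "unrelated")

INTERVAL_LEVELS <- c("I1", "I2", "I3")

#' Days-per-year conversion constant
#'
#' @return the default conversion used between continuous ages in years and
#'   post-transplant durations in days
#' @export
days_per_year_default <- function() 365.25

#' Coerce and validate a cohort table
#'
#' Validates the schema (required columns, unique ids, `exit_age_x >
#' transplant_age_j`, binary event indicator, donor-source levels) and the
#' consistency of `post_transplant_days` with the age difference (within
#' 1 day). If `post_transplant_days` is absent it is derived.
#'
#' @param df a data.frame in the cohort schema
#' @param days_per_year conversion constant, default 365.25
#' @return a validated `cohort` data.frame with an `interval` factor column
#'   (`I1`: t <= 100 days, `I2`: 100 < t <= 365, `I3`: t > 365)
#' @export
as_cohort <- function(df, days_per_year = days_per_year_default()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"post_transplant_days" %in% names(df) &&
      all(c("exit_age_x", "transplant_age_j") %in% names(df)))
    df$post_transplant_days <-
      round((df$exit_age_x - df$transplant_age_j) * days_per_year)
  missing_cols <- setdiff(CORE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("cohort ids must be unique", call. = FALSE)
  if (!all(df$event_theta %in% c(0, 1)))
    stop("event_theta must be coded 0/1", call. = FALSE)
  bad_donor <- setdiff(unique(df$donor_source), DONOR_LEVELS)
  if (length(bad_donor))
    stop("invalid donor_source value(s): ",
         paste(bad_donor, collapse = ", "),
         " (expected related/unrelated)", call. = FALSE)
  bad_order <- which(!is.na(df$exit_age_x) & !is.na(df$transplant_age_j) &
                       df$exit_age_x <= df$transplant_age_j)
  if (length(bad_order))
    stop("exit_age_x must exceed transplant_age_j; violated at row(s) ",
         paste(utils::head(bad_order, 5), collapse = ", "), call. = FALSE)
  implied <- round((df$exit_age_x - df$transplant_age_j) * days_per_year)
  incons <- which(!is.na(df$post_transplant_days) &
                    abs(df$post_transplant_days - implied) > 1)
  if (length(incons))
    stop("post_transplant_days inconsistent with ages at row(s) ",
         paste(utils::head(incons, 5), collapse = ", "), call. = FALSE)
  df$interval <- categorize_interval(df$post_transplant_days)
  attr(df, "days_per_year") <- days_per_year
  class(df) <- c("cohort", "data.frame")
  df
}

#' Is an object a cohort table?
#' @param x object to test
#' @export
is_cohort <- function(x) inherits(x, "cohort")

#' Names of covariate columns present in a cohort
#' @param cohort a cohort table
#' @export
cohort_covariates <- function(cohort) {
  intersect(COVARIATE_NAMES, names(cohort))
}

#' Categorize post-transplant duration into time-lapse intervals
#'
#' The three post-transplant survival intervals, with right-closed
#' boundaries: `I1` for t <= 100 days, `I2` for 100 < t <= 365 days, `I3`
#' for t > 365 days.
#'
#' @param post_transplant_days duration(s) in days, > 0
#' @return factor with levels `I1`, `I2`, `I3`
#' @examples
#' categorize_interval(c(100, 101, 365, 366))
#' @export
categorize_interval <- function(post_transplant_days) {
  if (any(is.na(post_transplant_days)))
    stop("post_transplant_days contains missing values", call. = FALSE)
  if (any(post_transplant_days <= 0))
    stop("post-transplant duration must be positive", call. = FALSE)
  cut(post_transplant_days, breaks = c(0, 100, 365, Inf),
      labels = INTERVAL_LEVELS, right = TRUE)
}

#' Apply study eligibility filters
#'
#' Retains patients with exit age above 30 years, transplant age below 70
#' years, and no missing required field (core columns plus any covariate
#' column present in the table; records with missing covariates are
#' excluded rather than imputed). Each excluded record is counted once,
#' under the first failing reason in the order `exit_age`,
#' `transplant_age`, `missing`.
#'
#' @param cohort a cohort table
#' @param min_exit_age exclusive lower bound on exit age (default 30)
#' @param max_transplant_age exclusive upper bound on transplant age
#'   (default 70)
#' @return list with elements `cohort` (the filtered table) and
#'   `exclusions` (named counts by reason, plus `n_input` and `n_retained`)
#' @export
apply_eligibility_filters <- function(cohort, min_exit_age = 30,
                                      max_transplant_age = 70) {
  stopifnot(is_cohort(cohort))
  checked <- c(CORE_COLUMNS, cohort_covariates(cohort))
  any_missing <- Reduce(`|`, lapply(checked, function(cn) is.na(cohort[[cn]])))
  fail_exit <- !is.na(cohort$exit_age_x) & cohort$exit_age_x <= min_exit_age
  fail_entry <- !is.na(cohort$transplant_age_j) &
    cohort$transplant_age_j >= max_transplant_age
  reason <- rep(NA_character_, nrow(cohort))
  reason[any_missing] <- "missing"
  reason[fail_entry] <- "transplant_age"
  reason[fail_exit] <- "exit_age"
  keep <- is.na(reason)
  out <- cohort[keep, , drop = FALSE]
  if (!nrow(out))
    warning("all records excluded by eligibility filters", call. = FALSE)
  exclusions <- list(
    n_input = nrow(cohort),
    n_retained = nrow(out),
    exit_age = sum(reason == "exit_age", na.rm = TRUE),
    transplant_age = sum(reason == "transplant_age", na.rm = TRUE),
    missing = sum(reason == "missing", na.rm = TRUE))
  attr(out, "days_per_year") <- attr(cohort, "days_per_year")
  class(out) <- class(cohort)
  list(cohort = out, exclusions = exclusions)
}

#' Read a cohort from a delimited text file
#'
#' Comma-separated UTF-8 with a header row in the cohort schema
#' (`event_theta` coded 1/0, `donor_source` coded related/unrelated).
#'
#' @param path file path
#' @param days_per_year conversion constant
#' @return a validated cohort table
#' @export
read_cohort <- function(path, days_per_year = days_per_year_default()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CORE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("cohort file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cn in c("transplant_age_j", "exit_age_x", "event_theta",
               "post_transplant_days", "transplant_year")) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("unparseable value in column '", cn, "' at data row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      df[[cn]] <- parsed
    }
  }
  as_cohort(df, days_per_year = days_per_year)
}

#' Write a cohort to a delimited text file
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips losslessly.
#'
#' @param cohort a cohort table
#' @param path file path
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is_cohort(cohort))
  out <- as.data.frame(cohort)[, setdiff(names(cohort), "interval"),
                               drop = FALSE]
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x), " patients (",
      sum(x$donor_source == "related"), " related, ",
      sum(x$donor_source == "unrelated"), " unrelated); ",
      sum(x$event_theta), " deaths\n", sep = "")
  cat("  covariates: ", paste(cohort_covariates(x), collapse = ", "),
      "\n", sep = "")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}
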