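# Exposure quantification: joint-years and use-pattern gradations.

frequency_levels <- c("daily", "weekly_not_daily", "two_three_per_month",
                      "less_often", "none")
mode_levels <- c("smoked", "other")
other_mode_levels <- c("vaping", "topical", "edible")

#' Representative days of use per year by frequency category
#'
#' Interview instruments record frequency as categories; simulation and
#' exposure arithmetic need days/year. These constants are configuration
#' (packaged YAML), not fixed truth: daily = 365, at least weekly but not
#' daily = 104 (about twice a week), 2-3 times per month = 30, less often
#' = 12, none = 0.
#'
#' @param path optional alternative YAML file with a `frequency_days`
#'   mapping.
#' @return named numeric vector over the frequency categories.
#' @export
frequency_days_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exposure_config.yaml",
                                package = "cannaphen")
  cfg <- yaml::read_yaml(path)
  out <- unlist(cfg$frequency_days)
  missing_lv <- setdiff(frequency_levels, names(out))
  if (length(missing_lv)) {
    abort(sprintf("Frequency-days config missing categories: %s",
                  paste(missing_lv, collapse = ", ")),
          class = "cannaphen_config_error")
  }
  out[frequency_levels]
}

#' Joint-years of marijuana exposure
#'
#' One joint-year is one joint per day for 365 days, the marijuana
#' analogue of tobacco pack-years. Over a single-year recall window the
#' exposure is `joints_per_day * days_used / 365`; only smoked use has a
#' joint equivalent (edibles, vaping and topicals contribute nothing
#' here).
#'
#' @param joints_per_day average joints smoked on a use day (>= 0).
#' @param days_used days of use within the window, in
#'   `[0, window_days]`.
#' @param window_days recall window length, default 365.
#' @return joint-years (dimensionless), vectorized over the inputs.
#' @export
#' @examples
#' joint_years(1, 365) # 1
#' joint_years(2, 73)  # 0.4
joint_years <- function(joints_per_day, days_used, window_days = 365L) {
  if (any(is.na(joints_per_day)) || any(joints_per_day < 0)) {
    abort("`joints_per_day` must be non-negative.",
          class = "cannaphen_validation_error")
  }
  if (any(is.na(days_used)) || any(days_used < 0)) {
    abort("`days_used` must be non-negative.",
          class = "cannaphen_validation_error")
  }
  if (any(days_used > window_days)) {
    abort(sprintf("`days_used` exceeds the %d-day window.", window_days),
          class = "cannaphen_validation_error")
  }
  joints_per_day * days_used / 365
}

#' Validate exposure records
#'
#' Checks the exposure-record contract: known category levels,
#' non-negative joints/day, days in \[0, 365\], and `days_used_past_year
#' == 0` exactly when `frequency_category == "none"`.
#'
#' @param records an exposure tibble with columns `patient_id`,
#'   `primary_mode`, `frequency_category`, `joints_per_day`,
#'   `days_used_past_year`, `other_modes` (list-column or
#'   semicolon-separated strings).
#' @return the records, invisibly, or an error.
#' @export
validate_exposures <- function(records) {
  if (!all(records$primary_mode %in% mode_levels)) {
    abort("Unknown primary_mode.", class = "cannaphen_validation_error")
  }
  if (!all(records$frequency_category %in% frequency_levels)) {
    abort("Unknown frequency_category.", class = "cannaphen_validation_error")
  }
  if (any(records$joints_per_day < 0)) {
    abort("joints_per_day must be >= 0.", class = "cannaphen_validation_error")
  }
  if (any(records$days_used_past_year < 0 |
            records$days_used_past_year > 365)) {
    abort("days_used_past_year must lie in [0, 365].",
          class = "cannaphen_validation_error")
  }
  none <- records$frequency_category == "none"
  if (any(xor(none, records$days_used_past_year == 0))) {
    abort("days_used_past_year must be 0 exactly when frequency is `none`.",
          class = "cannaphen_validation_error")
  }
  invisible(records)
}

#' Mean joint-years across exposure records
#'
#' Arithmetic mean of per-record joint-years. Callers restrict the
#' records to the subpopulation of interest (typically current smokers)
#' before averaging.
#'
#' @param records a validated exposure tibble.
#' @return a single number.
#' @export
mean_joint_years <- function(records) {
  if (nrow(records) == 0) {
    abort("Mean joint-years undefined on an empty record set.",
          class = "cannaphen_undefined_rate_error")
  }
  validate_exposures(records)
  mean(joint_years(records$joints_per_day, records$days_used_past_year))
}

#' Use-pattern summary among current users
#'
#' Distribution of frequency categories and of the predominant mode
#' (smoked vs other forms only), plus the share of smokers also using
#' other forms. Percentages are rounded half-up to one decimal.
#'
#' @param records exposure records for current (past-30-day) users.
#' @return a list with tibbles `frequency` and `mode`, and
#'   `pct_smokers_with_other_modes`.
#' @export
use_pattern_summary <- function(records) {
  if (nrow(records) == 0) {
    abort("Use-pattern distribution undefined on an empty record set.",
          class = "cannaphen_undefined_rate_error")
  }
  validate_exposures(records)
  n <- nrow(records)
  freq <- tibble(
    frequency_category = frequency_levels,
    n = as.integer(table(factor(records$frequency_category,
                                levels = frequency_levels))),
  )
  freq$pct <- round_half_up(100 * freq$n / n, 1)
  mode <- tibble(
    primary_mode = mode_levels,
    n = as.integer(table(factor(records$primary_mode, levels = mode_levels)))
  )
  mode$pct <- round_half_up(100 * mode$n / n, 1)
  smokers <- records[records$primary_mode == "smoked", , drop = FALSE]
  other <- if (nrow(smokers) == 0) NA_real_ else {
    has_other <- vapply(smokers$other_modes, function(m) {
      if (is.character(m) && length(m) == 1 && !is.na(m)) {
        m <- split_semis(m)
      }
      length(m) > 0
    }, logical(1))
    round_half_up(100 * mean(has_other), 1)
  }
  list(frequency = freq, mode = mode, pct_smokers_with_other_modes = other)
}

#' Read / write exposure records CSV
#'
#' Columns: `patient_id`, `primary_mode`, `frequency_category`,
#' `joints_per_day`, `days_used_past_year`, `other_modes`
#' (semicolon-separated list).
#'
#' @param path an exposures CSV file.
#' @return `read_exposures()` returns a validated exposure tibble with
#'   `other_modes` as a list-column.
#' @export
read_exposures <- function(path) {
  raw <- read_csv_skip_comments(path)
  out <- tibble(
    patient_id = as.character(raw$patient_id),
    primary_mode = raw$primary_mode,
    frequency_category = raw$frequency_category,
    joints_per_day = as.numeric(raw$joints_per_day),
    days_used_past_year = as.integer(raw$days_used_past_year),
    other_modes = lapply(raw$other_modes, split_semis)
  )
  validate_exposures(out)
  out
}

#' @rdname read_exposures
#' @param records a validated exposure tibble.
#' @param seed optional seed recorded in the provenance header.
#' @export
write_exposures <- function(records, path, seed = NULL) {
  flat <- records
  flat$other_modes <- vapply(records$other_modes, paste, "", collapse = ";")
  write_csv_with_header(flat, path, seed = seed)
}
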