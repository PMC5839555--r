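# Cohort selection: ICD-9 diagnosis filter, age band, visit window.

#' ICD-9 lexical shape check
#'
#' Accepts numeric codes (3 digits with an optional dot and 1-2 more
#' digits) and V/E-prefixed codes. This is a shape check only; it does
#' not consult a code dictionary.
#'
#' @param x character vector of candidate codes.
#' @return logical vector.
#' @export
is_icd9 <- function(x) {
  grepl("^(\\d{3}(\\.\\d{1,2})?|V\\d{2}(\\.\\d{1,2})?|E\\d{3}(\\.\\d)?)$", x)
}

#' Conventional coronary-artery-disease ICD-9 roots
#'
#' The ischemic-heart-disease range 410-414. The precise code list used
#' in any given health system is configuration, not fixed truth; pass
#' your own set to [cohort_spec()] to override.
#'
#' @return character vector of 3-digit code roots.
#' @export
default_cad_codes <- function() {
  as.character(410:414)
}

#' Cohort selection specification
#'
#' Defines the registry filter: a coronary-artery-disease diagnosis (any
#' patient code whose exact value or 3-digit root is in `cad_codes`), an
#' age band at the index date, and at least one visit inside the window
#' (inclusive on both ends).
#'
#' @param cad_codes ICD-9 codes (or 3-digit roots) defining the
#'   diagnosis filter.
#' @param age_min,age_max inclusive age band in years.
#' @param visit_window_start,visit_window_end inclusive calendar window
#'   for the qualifying visit.
#' @return a `cannaphen_cohort_spec`.
#' @export
cohort_spec <- function(cad_codes = default_cad_codes(),
                        age_min = 65L, age_max = 67L,
                        visit_window_start = as.Date("2015-01-01"),
                        visit_window_end = as.Date("2015-12-31")) {
  if (length(cad_codes) == 0) {
    abort("`cad_codes` must not be empty.", class = "cannaphen_config_error")
  }
  if (!all(is_icd9(cad_codes))) {
    abort("`cad_codes` contains values that are not ICD-9-shaped.",
          class = "cannaphen_config_error")
  }
  age_min <- as.integer(age_min); age_max <- as.integer(age_max)
  if (age_min > age_max) {
    abort("`age_min` must be <= `age_max`.", class = "cannaphen_config_error")
  }
  visit_window_start <- as.Date(visit_window_start)
  visit_window_end <- as.Date(visit_window_end)
  if (visit_window_start > visit_window_end) {
    abort("Visit window start must be <= end.", class = "cannaphen_config_error")
  }
  structure(list(cad_codes = unique(as.character(cad_codes)),
                 age_min = age_min, age_max = age_max,
                 visit_window_start = visit_window_start,
                 visit_window_end = visit_window_end),
            class = "cannaphen_cohort_spec")
}

#' @export
print.cannaphen_cohort_spec <- function(x, ...) {
  cat("<cannaphen_cohort_spec>\n")
  cat("  diagnosis codes:", paste(x$cad_codes, collapse = ", "), "\n")
  cat(sprintf("  age band: %d-%d years\n", x$age_min, x$age_max))
  cat(sprintf("  visit window: %s .. %s (inclusive)\n",
              x$visit_window_start, x$visit_window_end))
  invisible(x)
}

code_matches <- function(codes, cad_codes) {
  roots <- sub("\\..*$", "", codes)
  any(codes %in% cad_codes | roots %in% cad_codes)
}

#' Select the study cohort from a patient registry
#'
#' A pure filter retaining patients who satisfy all of: a qualifying
#' diagnosis code, age within the band, and at least one visit inside
#' the window. Input order is preserved; vital status and contact
#' information play no role here (they matter only after arm sampling).
#'
#' @param patients a patient tibble (see [read_patients()]).
#' @param spec a [cohort_spec()].
#' @return the filtered patient tibble.
#' @export
select_cohort <- function(patients, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cannaphen_cohort_spec"))
  if (nrow(patients) == 0) return(patients)
  has_cad <- vapply(patients$diagnosis_codes, code_matches, logical(1),
                    cad_codes = spec$cad_codes)
  in_age <- patients$age_years >= spec$age_min &
    patients$age_years <= spec$age_max
  has_visit <- vapply(patients$visit_dates, function(v) {
    length(v) > 0 && any(v >= spec$visit_window_start &
                           v <= spec$visit_window_end)
  }, logical(1))
  patients[has_cad & in_age & has_visit, , drop = FALSE]
}
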