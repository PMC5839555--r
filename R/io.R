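# File interchange: notes JSONL, registry/interview/exposure CSV.
# Every file written by the package starts with a '#' provenance comment
# (tool version, seed, config hash); every reader skips '#' lines.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  parts <- c(
    sprintf("cannaphen %s", as.character(utils::packageVersion("cannaphen"))),
    if (!is.null(seed)) sprintf("seed=%s", seed),
    if (!is.null(config_hash)) sprintf("config=%s", config_hash)
  )
  paste0("# ", paste(parts, collapse = "; "))
}

# md5 of a config list, via its canonical JSON serialization
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

write_csv_with_header <- function(df, path, seed = NULL, config_hash = NULL) {
  writeLines(provenance_header(seed, config_hash), path)
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (inherits(df[[j]], "Date")) {
    df[[j]] <- format(df[[j]], "%Y-%m-%d")
  }
  suppressWarnings(utils::write.table(
    df, path, sep = ",", row.names = FALSE, col.names = TRUE,
    qmethod = "double", append = TRUE, na = ""
  ))
  invisible(path)
}

read_csv_skip_comments <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, col_types = readr::cols(.default = "c"))
}

#' Read clinical notes from JSONL
#'
#' One JSON object per line with fields `patient_id`, `note_id`, `date`,
#' `text`. Lines starting with `#` are treated as comments. Malformed
#' lines (unparseable JSON, missing fields, invalid dates, duplicate
#' note ids within a patient) raise an error naming the line.
#'
#' @param path a notes JSONL file.
#' @return a tibble of note records: `patient_id`, `note_id`,
#'   `note_date` (Date), `text`. An empty file yields an empty tibble
#'   with a warning.
#' @export
read_notes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Notes file not found: %s", path), class = "cannaphen_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warn(sprintf("Notes file is empty: %s", path))
    return(tibble(patient_id = character(), note_id = character(),
                  note_date = as.Date(character()), text = character()))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(obj)) {
      abort(sprintf("Line %d of %s is not valid JSON.", lineno[i], path),
            class = "cannaphen_parse_error")
    }
    for (f in c("patient_id", "note_id", "date", "text")) {
      if (is.null(obj[[f]])) {
        abort(sprintf("Line %d of %s: missing required field `%s`.",
                      lineno[i], path, f),
              class = "cannaphen_parse_error")
      }
    }
    d <- parse_iso_date(as.character(obj$date))
    if (is.na(d)) {
      abort(sprintf("Line %d of %s: unparseable date \"%s\".",
                    lineno[i], path, obj$date),
            class = "cannaphen_parse_error")
    }
    recs[[i]] <- tibble(patient_id = as.character(obj$patient_id),
                        note_id = as.character(obj$note_id),
                        note_date = d, text = as.character(obj$text))
  }
  out <- dplyr::bind_rows(recs)
  dup <- duplicated(out[, c("patient_id", "note_id")])
  if (any(dup)) {
    abort(sprintf("Duplicate note_id within patient at line(s): %s",
                  paste(lineno[dup], collapse = ", ")),
          class = "cannaphen_parse_error")
  }
  out
}

#' Write clinical notes to JSONL
#' @param notes a note-record tibble (`patient_id`, `note_id`,
#'   `note_date`, `text`).
#' @param path output file.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path, seed = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  for (i in seq_len(nrow(notes))) {
    writeLines(jsonlite::toJSON(list(
      patient_id = notes$patient_id[i], note_id = notes$note_id[i],
      date = format(notes$note_date[i], "%Y-%m-%d"), text = notes$text[i]
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a patient registry CSV
#'
#' Columns: `patient_id`, `age_years`, `diagnosis_codes`
#' (semicolon-separated ICD-9 strings), `visit_dates` (semicolon-separated
#' ISO dates), `deceased`, `has_contact_info`. Validation failures are
#' reported with row numbers.
#'
#' @param path a patients CSV file.
#' @return a tibble with list-columns `diagnosis_codes` and
#'   `visit_dates`.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Patients file not found: %s", path), class = "cannaphen_io_error")
  }
  raw <- read_csv_skip_comments(path)
  if (nrow(raw) == 0) {
    warn(sprintf("Patients file is empty: %s", path))
    return(empty_patients())
  }
  need <- c("patient_id", "age_years", "diagnosis_codes", "visit_dates",
            "deceased", "has_contact_info")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("Patients file %s is missing column(s): %s", path,
                  paste(miss, collapse = ", ")),
          class = "cannaphen_parse_error")
  }
  age <- suppressWarnings(as.integer(raw$age_years))
  if (anyNA(age) || any(age < 0)) {
    bad <- which(is.na(age) | age < 0)
    abort(sprintf("Invalid age_years at data row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "cannaphen_parse_error")
  }
  codes <- lapply(raw$diagnosis_codes, split_semis)
  badc <- which(!vapply(codes, function(cc) all(is_icd9(cc)), logical(1)))
  if (length(badc)) {
    abort(sprintf("Diagnosis code not ICD-9-shaped at data row(s): %s",
                  paste(badc, collapse = ", ")),
          class = "cannaphen_parse_error")
  }
  visits <- lapply(raw$visit_dates, function(v) parse_iso_date(split_semis(v)))
  badv <- which(vapply(visits, anyNA, logical(1)))
  if (length(badv)) {
    abort(sprintf("Unparseable visit date at data row(s): %s",
                  paste(badv, collapse = ", ")),
          class = "cannaphen_parse_error")
  }
  patients <- tibble(
    patient_id = as.character(raw$patient_id),
    age_years = age,
    diagnosis_codes = codes,
    visit_dates = visits,
    deceased = parse_bool(raw$deceased),
    has_contact_info = parse_bool(raw$has_contact_info)
  )
  if (anyDuplicated(patients$patient_id)) {
    abort("Duplicate patient_id in registry.", class = "cannaphen_parse_error")
  }
  patients
}

empty_patients <- function() {
  tibble(patient_id = character(), age_years = integer(),
         diagnosis_codes = list(), visit_dates = list(),
         deceased = logical(), has_contact_info = logical())
}

parse_bool <- function(x) {
  v <- tolower(as.character(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    abort("Boolean column contains values other than TRUE/FALSE.",
          class = "cannaphen_parse_error")
  }
  out
}

#' Write a patient registry CSV
#' @inheritParams write_notes
#' @param patients a patient tibble as returned by [read_patients()].
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path, seed = NULL) {
  flat <- tibble(
    patient_id = patients$patient_id,
    age_years = patients$age_years,
    diagnosis_codes = vapply(patients$diagnosis_codes, paste, "", collapse = ";"),
    visit_dates = vapply(patients$visit_dates,
                         function(v) paste(format(v, "%Y-%m-%d"), collapse = ";"),
                         ""),
    deceased = patients$deceased,
    has_contact_info = patients$has_contact_info
  )
  write_csv_with_header(flat, path, seed = seed)
}

#' Read interview responses from CSV
#'
#' Required columns: `patient_id`, `completed`, `used_past_30d`,
#' `used_past_year`, `ever_used`; any further columns are carried along
#' as covariates. The recall-window nesting invariant
#' (past 30 days => past year => ever) is enforced for completed rows.
#'
#' @param path an interviews CSV file.
#' @return a tibble of interview responses.
#' @export
read_interviews <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Interviews file not found: %s", path), class = "cannaphen_io_error")
  }
  raw <- read_csv_skip_comments(path)
  need <- c("patient_id", "completed", "used_past_30d", "used_past_year",
            "ever_used")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("Interviews file %s is missing column(s): %s", path,
                  paste(miss, collapse = ", ")),
          class = "cannaphen_parse_error")
  }
  out <- raw
  for (f in c("completed", "used_past_30d", "used_past_year", "ever_used")) {
    out[[f]] <- parse_bool(raw[[f]])
  }
  for (f in setdiff(names(out), need)) {
    num <- suppressWarnings(as.numeric(out[[f]]))
    if (!anyNA(num[!is.na(out[[f]])])) out[[f]] <- num
  }
  validate_interviews(out)
  as_tibble(out)
}

validate_interviews <- function(interviews) {
  cc <- interviews$completed
  bad <- cc & (
    (interviews$used_past_30d & !interviews$used_past_year) |
      (interviews$used_past_year & !interviews$ever_used)
  )
  if (any(bad)) {
    abort(sprintf(
      "Recall-window nesting violated (past-30d => past-year => ever) for: %s",
      paste(interviews$patient_id[bad], collapse = ", ")),
      class = "cannaphen_validation_error")
  }
  invisible(interviews)
}

#' @rdname read_interviews
#' @inheritParams write_notes
#' @param interviews an interview tibble.
#' @export
write_interviews <- function(interviews, path, seed = NULL) {
  write_csv_with_header(interviews, path, seed = seed)
}
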