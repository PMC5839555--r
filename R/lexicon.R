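# Lexicon: the term set that drives mention detection, and the matcher.

#' Compile a search lexicon
#'
#' Builds a validated lexicon from term specifications. Each term has a
#' `surface` form (stored lowercase), an `enabled` flag, and a free-text
#' `note` recording why it is in (or out of) the active set. Disabled
#' terms are retained for documentation and can be re-enabled, so a
#' discard decision (e.g. dropping "mj" because it collides with the
#' temporomandibular-joint abbreviation TMJ) stays auditable.
#'
#' @param term_specs a data frame with columns `surface`, and optionally
#'   `enabled` (default `TRUE`) and `note`, or a list of lists with those
#'   fields.
#' @param case_sensitive should matching respect case? Default `FALSE`:
#'   clinical notes mix "MARIJUANA", "Cannabis" and lowercase freely.
#' @return an object of class `cannaphen_lexicon` with a `terms` tibble
#'   and the matching policy (whole-word).
#' @export
#' @examples
#' compile_lexicon(data.frame(surface = c("marijuana", "cannabis")))
compile_lexicon <- function(term_specs, case_sensitive = FALSE) {
  if (is.data.frame(term_specs)) {
    specs <- as_tibble(term_specs)
  } else if (is.list(term_specs) && length(term_specs) > 0) {
    specs <- dplyr::bind_rows(lapply(term_specs, function(t) {
      tibble(surface = t$surface %||% NA_character_,
             enabled = t$enabled %||% TRUE,
             note = t$note %||% "")
    }))
  } else {
    abort("`term_specs` must be a non-empty data frame or list of term specs.",
          class = "cannaphen_validation_error")
  }
  if (nrow(specs) == 0) {
    abort("Lexicon needs at least one term.", class = "cannaphen_validation_error")
  }
  if (!"enabled" %in% names(specs)) specs$enabled <- TRUE
  if (!"note" %in% names(specs)) specs$note <- ""
  specs$enabled <- as.logical(specs$enabled)
  specs$note <- as.character(specs$note)

  surface <- as.character(specs$surface)
  if (anyNA(surface) || any(!nzchar(trimws(surface)))) {
    abort("Every term needs a non-empty `surface`.",
          class = "cannaphen_validation_error")
  }
  if (any(grepl("\\s", surface))) {
    abort("Term surfaces must not contain whitespace.",
          class = "cannaphen_validation_error")
  }
  surface <- stringi::stri_trans_nfc(tolower(surface))
  if (anyDuplicated(surface)) {
    dup <- unique(surface[duplicated(surface)])
    abort(sprintf("Duplicate term surface(s) after case-folding: %s",
                  paste(dup, collapse = ", ")),
          class = "cannaphen_validation_error")
  }
  terms <- tibble(surface = surface, enabled = specs$enabled, note = specs$note)
  if (!any(terms$enabled)) {
    warn("Lexicon has no enabled terms; matching will find nothing.")
  }
  structure(
    list(terms = terms, match_policy = "whole_word",
         case_sensitive = isTRUE(case_sensitive)),
    class = "cannaphen_lexicon"
  )
}

#' The default marijuana lexicon
#'
#' "marijuana", "cannabis" and "mjx" enabled; "mj" present but disabled
#' because of its overlap with temporomandibular-joint (TMJ)
#' abbreviations. Loaded from the packaged YAML config so the term set is
#' data, not code.
#'
#' @return a `cannaphen_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yaml", package = "cannaphen"))
}

#' Read / write a lexicon YAML config
#'
#' The config is a YAML document with a `terms` list of
#' `{surface, enabled, note}` entries and an optional `case_sensitive`
#' flag.
#'
#' @param path path to a YAML lexicon file.
#' @return `read_lexicon()` returns a `cannaphen_lexicon`;
#'   `write_lexicon()` returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Lexicon file not found: %s", path),
          class = "cannaphen_io_error")
  }
  cfg <- yaml::read_yaml(path)
  compile_lexicon(cfg$terms, case_sensitive = isTRUE(cfg$case_sensitive))
}

#' @rdname read_lexicon
#' @param lexicon a `cannaphen_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "cannaphen_lexicon"))
  cfg <- list(
    case_sensitive = lexicon$case_sensitive,
    terms = lapply(seq_len(nrow(lexicon$terms)), function(i) {
      as.list(lexicon$terms[i, c("surface", "enabled", "note")])
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.cannaphen_lexicon <- function(x, ...) {
  on <- x$terms$surface[x$terms$enabled]
  off <- x$terms$surface[!x$terms$enabled]
  cat("<cannaphen_lexicon> whole-word,",
      if (x$case_sensitive) "case-sensitive" else "case-insensitive", "\n")
  cat("  enabled: ", paste(on, collapse = ", "), "\n", sep = "")
  if (length(off)) cat("  disabled:", paste(off, collapse = ", "), "\n")
  invisible(x)
}

#' Enabled surfaces of a lexicon
#' @param lexicon a `cannaphen_lexicon`.
#' @return character vector of enabled term surfaces.
#' @export
enabled_terms <- function(lexicon) {
  stopifnot(inherits(lexicon, "cannaphen_lexicon"))
  lexicon$terms$surface[lexicon$terms$enabled]
}

# Word boundary = alphanumeric / non-alphanumeric transition. Digits count
# as word characters, so "mjx2" does not contain a whole-word "mjx" and
# "TMJ" never matches "mj". Hyphens and line breaks are boundaries and are
# never bridged ("mari-\njuana" does not match "marijuana").
.term_pattern <- function(term) {
  esc <- gsub("([][^$.|?*+(){}\\\\-])", "\\\\\\1", term)
  paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])")
}

#' Locate lexicon-term mentions in note text
#'
#' Finds every non-overlapping whole-word occurrence of every enabled
#' term. A mention is counted whatever its assertion status — negated
#' ("denies marijuana use") and historical phrases still match. This
#' negation blindness is deliberate: the phenotype treats any mention of
#' the substance as a signal of current or former use, and the validation
#' statistics then quantify how often that premise holds.
#'
#' Offsets are 0-based character positions with exclusive `end`, so
#' `substr(text, start + 1, end)` recovers `matched_text`. Text is
#' NFC-normalized before matching; mentions are returned sorted by
#' `start`.
#'
#' @param notes a note record: a data frame with columns `patient_id`,
#'   `note_id`, `note_date`, `text` (one or many rows).
#' @param lexicon a `cannaphen_lexicon`.
#' @return a tibble of mentions with columns `patient_id`, `note_id`,
#'   `note_date`, `term`, `start`, `end`, `matched_text`; zero rows when
#'   nothing matches.
#' @export
#' @examples
#' lex <- default_lexicon()
#' note <- tibble::tibble(patient_id = "P1", note_id = "N1",
#'                        note_date = as.Date("2015-06-01"),
#'                        text = "Pt reports smoking MARIJUANA; denies mjx.")
#' find_mentions(note, lex)
find_mentions <- function(notes, lexicon) {
  stopifnot(inherits(lexicon, "cannaphen_lexicon"))
  notes <- as_tibble(notes)
  empty <- tibble(patient_id = character(), note_id = character(),
                  note_date = as.Date(character()), term = character(),
                  start = integer(), end = integer(),
                  matched_text = character())
  if (nrow(notes) == 0) return(empty)
  text <- stringi::stri_trans_nfc(ifelse(is.na(notes$text), "", notes$text))

  hits <- list()
  for (term in enabled_terms(lexicon)) {
    m <- gregexpr(.term_pattern(term), text, perl = TRUE,
                  ignore.case = !lexicon$case_sensitive)
    for (i in seq_along(m)) {
      pos <- m[[i]]
      if (pos[1] == -1L) next
      len <- attr(pos, "match.length")
      hits[[length(hits) + 1L]] <- tibble(
        patient_id = notes$patient_id[i],
        note_id = notes$note_id[i],
        note_date = notes$note_date[i],
        term = term,
        start = as.integer(pos) - 1L,
        end = as.integer(pos) - 1L + as.integer(len),
        matched_text = substring(text[i], pos, pos + len - 1L),
        .row = i
      )
    }
  }
  if (length(hits) == 0) return(empty)
  out <- dplyr::bind_rows(hits)
  out <- out[order(out$.row, out$start, out$end), , drop = FALSE]
  # Defensive non-overlap filter within each note (whole-word matches of
  # distinct single-word terms cannot in fact overlap).
  keep <- logical(nrow(out))
  last_row <- -1L
  last_end <- -1L
  for (k in seq_len(nrow(out))) {
    if (out$.row[k] != last_row || out$start[k] >= last_end) {
      keep[k] <- TRUE
      last_row <- out$.row[k]
      last_end <- out$end[k]
    }
  }
  out <- out[keep, setdiff(names(out), ".row"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write mentions to CSV
#'
#' Columns: patient_id, note_id, note_date, term, start, end,
#' matched_text. A `#` provenance header line is prepended.
#'
#' @param mentions a mentions tibble from [find_mentions()].
#' @param path output file.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path, seed = NULL) {
  write_csv_with_header(mentions, path, seed = seed)
}
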