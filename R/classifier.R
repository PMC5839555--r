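# The core phenotype: mention-in-lookback classification and arm sampling.

# The "past 12 months" lookback is the lookback_days calendar days ending
# at and including index_date: [index_date - lookback_days + 1, index_date].
lookback_window <- function(index_date, lookback_days) {
  c(start = index_date - lookback_days + 1L, end = index_date)
}

#' Classify one patient from their notes
#'
#' A patient is a *preliminary user* iff any enabled lexicon term has a
#' whole-word mention in any of their notes dated inside the lookback
#' window, and a *preliminary non-user* otherwise — including patients
#' with no notes at all (absence of evidence classifies as non-use;
#' the interview is the arbiter later). Mentions outside the window are
#' ignored and not retained.
#'
#' @param patient_id the patient the notes belong to.
#' @param notes a note tibble; all rows must carry `patient_id`.
#' @param lexicon a `cannaphen_lexicon`.
#' @param index_date the study anchor date; the window is the
#'   `lookback_days` days ending at and including it.
#' @param lookback_days positive integer, default 365.
#' @return a one-row classification tibble: `patient_id`, `label`
#'   (`"preliminary_user"` / `"preliminary_nonuser"`),
#'   `n_supporting_mentions`, `first_mention_date`, and a `mentions`
#'   list-column holding the supporting mentions.
#' @export
classify_patient <- function(patient_id, notes, lexicon,
                             index_date, lookback_days = 365L) {
  index_date <- as.Date(index_date)
  lookback_days <- as.integer(lookback_days)
  if (is.na(lookback_days) || lookback_days <= 0) {
    abort("`lookback_days` must be a positive integer.",
          class = "cannaphen_config_error")
  }
  notes <- as_tibble(notes)
  if (nrow(notes) > 0 && !all(notes$patient_id == patient_id)) {
    abort("All notes passed to classify_patient() must belong to `patient_id`.",
          class = "cannaphen_validation_error")
  }
  classify_cohort(tibble(patient_id = patient_id), notes, lexicon,
                  index_date, lookback_days)
}

#' Classify every cohort patient
#'
#' Applies [classify_patient()]'s rule across a cohort. Patients with
#' zero notes are classified (as non-users), not dropped. Notes whose
#' `patient_id` is not in the cohort are ignored with a warning.
#'
#' @param cohort a patient tibble (only `patient_id` is used); ids must
#'   be unique.
#' @inheritParams classify_patient
#' @return a classification tibble, one row per cohort patient, in
#'   cohort order.
#' @export
classify_cohort <- function(cohort, notes, lexicon,
                            index_date, lookback_days = 365L) {
  index_date <- as.Date(index_date)
  lookback_days <- as.integer(lookback_days)
  if (is.na(lookback_days) || lookback_days <= 0) {
    abort("`lookback_days` must be a positive integer.",
          class = "cannaphen_config_error")
  }
  ids <- cohort$patient_id
  if (anyDuplicated(ids)) {
    abort("Cohort patient_ids must be unique.",
          class = "cannaphen_validation_error")
  }
  notes <- as_tibble(notes)
  if (nrow(notes) > 0) {
    stray <- !notes$patient_id %in% ids
    if (any(stray)) {
      warn(sprintf("Ignoring %d note(s) for patients outside the cohort.",
                   sum(stray)))
      notes <- notes[!stray, , drop = FALSE]
    }
  }
  win <- lookback_window(index_date, lookback_days)
  in_window <- notes[notes$note_date >= win["start"] &
                       notes$note_date <= win["end"], , drop = FALSE]
  mentions <- find_mentions(in_window, lexicon)
  by_patient <- split(mentions, factor(mentions$patient_id, levels = ids))
  n_m <- unname(vapply(by_patient, nrow, integer(1)))
  first_date <- as.Date(unname(vapply(by_patient, function(m) {
    if (nrow(m) == 0) NA_character_ else format(min(m$note_date), "%Y-%m-%d")
  }, character(1))))
  tibble(
    patient_id = ids,
    label = ifelse(n_m > 0, "preliminary_user", "preliminary_nonuser"),
    n_supporting_mentions = n_m,
    first_mention_date = first_date,
    index_date = index_date,
    lookback_days = lookback_days,
    mentions = unname(by_patient)
  )
}

#' Write classifications to CSV
#' @param classifications a classification tibble from [classify_cohort()].
#' @param path output file.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path, seed = NULL) {
  flat <- classifications[, c("patient_id", "label", "n_supporting_mentions",
                              "first_mention_date")]
  write_csv_with_header(flat, path, seed = seed)
}

#' Read classifications from CSV
#' @param path a classifications CSV written by [write_classifications()].
#' @return a tibble with `patient_id`, `label`, `n_supporting_mentions`,
#'   `first_mention_date`.
#' @export
read_classifications <- function(path) {
  raw <- read_csv_skip_comments(path)
  need <- c("patient_id", "label")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("Classifications file missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "cannaphen_parse_error")
  }
  if (!all(raw$label %in% c("preliminary_user", "preliminary_nonuser"))) {
    abort("Unknown classification label.", class = "cannaphen_parse_error")
  }
  out <- tibble(patient_id = as.character(raw$patient_id), label = raw$label)
  if ("n_supporting_mentions" %in% names(raw)) {
    out$n_supporting_mentions <- as.integer(raw$n_supporting_mentions)
  }
  if ("first_mention_date" %in% names(raw)) {
    out$first_mention_date <- parse_iso_date(raw$first_mention_date)
  }
  out
}

# Single source of truth for the seeded uniform without-replacement draw,
# shared by sample_arms() and the exact-count generator so planted
# exclusions land on the ids the draw will actually select.
draw_arm_ids <- function(user_ids, nonuser_ids, n_per_arm, seed) {
  withr::with_seed(as.integer(seed), {
    list(users = sample(user_ids, n_per_arm),
         nonusers = sample(nonuser_ids, n_per_arm))
  })
}

#' Sample the two study arms with post-sampling exclusions
#'
#' Draws `n_per_arm` patients uniformly without replacement from each
#' preliminary arm using the seeded generator, *then* removes sampled
#' patients who are deceased, then sets aside sampled patients without
#' contact information. The order (sample first, exclude after) mirrors
#' typical recruitment accounting: exclusions come out of the drawn
#' sample, not the sampling frame.
#'
#' @param classifications a classification tibble (from
#'   [classify_cohort()] or [read_classifications()]).
#' @param patients the patient registry carrying `deceased` and
#'   `has_contact_info`.
#' @param n_per_arm patients to draw per arm (default 51).
#' @param seed integer seed; recorded in the result.
#' @return a `cannaphen_arm_sample`: `users` and `nonusers` are the
#'   contactable final arms; `excluded_deceased` and
#'   `excluded_no_contact` list the removed ids.
#' @export
sample_arms <- function(classifications, patients, n_per_arm = 51L, seed) {
  n_per_arm <- as.integer(n_per_arm)
  user_ids <- classifications$patient_id[
    classifications$label == "preliminary_user"]
  nonuser_ids <- classifications$patient_id[
    classifications$label == "preliminary_nonuser"]
  for (arm in list(c("user", length(user_ids)),
                   c("non-user", length(nonuser_ids)))) {
    if (as.integer(arm[2]) < n_per_arm) {
      abort(sprintf("The %s arm has only %s members; %d requested.",
                    arm[1], arm[2], n_per_arm),
            class = "cannaphen_validation_error")
    }
  }
  drawn <- draw_arm_ids(user_ids, nonuser_ids, n_per_arm, seed)
  status <- patients[match(c(drawn$users, drawn$nonusers),
                           patients$patient_id), ]
  if (anyNA(status$patient_id)) {
    abort("Sampled patient missing from registry.",
          class = "cannaphen_validation_error")
  }
  dec <- status$patient_id[status$deceased]
  alive_u <- setdiff(drawn$users, dec)
  alive_n <- setdiff(drawn$nonusers, dec)
  no_contact <- status$patient_id[!status$deceased & !status$has_contact_info]
  structure(list(
    users = setdiff(alive_u, no_contact),
    nonusers = setdiff(alive_n, no_contact),
    excluded_deceased = dec,
    excluded_no_contact = no_contact,
    sampled_users = drawn$users,
    sampled_nonusers = drawn$nonusers,
    n_per_arm = n_per_arm,
    seed = as.integer(seed)
  ), class = "cannaphen_arm_sample")
}

#' @export
print.cannaphen_arm_sample <- function(x, ...) {
  cat("<cannaphen_arm_sample> seed", x$seed, "\n")
  cat(sprintf("  drawn: %d users + %d non-users\n",
              length(x$sampled_users), length(x$sampled_nonusers)))
  cat(sprintf("  deceased removed: %d -> %d retained\n",
              length(x$excluded_deceased),
              length(x$sampled_users) + length(x$sampled_nonusers) -
                length(x$excluded_deceased)))
  cat(sprintf("  without contact info: %d -> %d contactable (%d users, %d non-users)\n",
              length(x$excluded_no_contact),
              length(x$users) + length(x$nonusers),
              length(x$users), length(x$nonusers)))
  invisible(x)
}

#' Contactable patients of an arm sample
#' @param arms a `cannaphen_arm_sample`.
#' @return character vector of ids across both final arms.
#' @export
contactable_ids <- function(arms) {
  stopifnot(inherits(arms, "cannaphen_arm_sample"))
  c(arms$users, arms$nonusers)
}
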