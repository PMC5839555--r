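index_date <- as.Date("2015-12-31")

test_that("classification hinges on an in-window mention", {
  lex <- default_lexicon()
  hit <- classify_patient("P1",
                          make_note("P1", "cannabis use discussed", index_date - 30),
                          lex, index_date)
  expect_equal(hit$label, "preliminary_user")
  expect_equal(hit$n_supporting_mentions, 1L)
  expect_equal(hit$mentions[[1]]$term, "cannabis")

  old <- classify_patient("P1",
                          make_note("P1", "marijuana use discussed", index_date - 400),
                          lex, index_date)
  expect_equal(old$label, "preliminary_nonuser")
  expect_equal(old$n_supporting_mentions, 0L)

  none <- classify_patient("P1", make_note("P1", "x", index_date)[0, ], lex, index_date)
  expect_equal(none$label, "preliminary_nonuser")
})

test_that("the 365-day window includes index_date - 364 and excludes -365", {
  lex <- default_lexicon()
  inside <- classify_patient("P1",
                             make_note("P1", "mjx", index_date - 364), lex, index_date)
  outside <- classify_patient("P1",
                              make_note("P1", "mjx", index_date - 365), lex, index_date)
  at_index <- classify_patient("P1",
                               make_note("P1", "mjx", index_date), lex, index_date)
  expect_equal(inside$label, "preliminary_user")
  expect_equal(outside$label, "preliminary_nonuser")
  expect_equal(at_index$label, "preliminary_user")
})

test_that("cohort classification keeps zero-note patients and ignores strays", {
  lex <- default_lexicon()
  cohort <- tibble::tibble(patient_id = c("A", "B", "C"))
  notes <- dplyr::bind_rows(
    make_note("A", "smokes marijuana", index_date - 10),
    make_note("Z", "cannabis", index_date - 10, note_id = "Z-N1"))
  expect_warning(cls <- classify_cohort(cohort, notes, lex, index_date),
                 "outside the cohort")
  expect_equal(cls$patient_id, c("A", "B", "C"))
  expect_equal(cls$label,
               c("preliminary_user", "preliminary_nonuser", "preliminary_nonuser"))

  # all-disabled lexicon classifies everyone as non-user
  suppressWarnings(off <- compile_lexicon(data.frame(surface = "marijuana",
                                                     enabled = FALSE)))
  cls_off <- classify_cohort(cohort, notes[1, ], lex = off, index_date)
  expect_true(all(cls_off$label == "preliminary_nonuser"))

  expect_error(classify_cohort(tibble::tibble(patient_id = c("A", "A")),
                               notes[1, ], lex, index_date),
               class = "cannaphen_validation_error")
  expect_error(classify_cohort(cohort, notes[1, ], lex, index_date,
                               lookback_days = 0),
               class = "cannaphen_config_error")
})

test_that("classification is monotone and idempotent under added/duplicated notes", {
  lex <- default_lexicon()
  cohort <- tibble::tibble(patient_id = sprintf("P%02d", 1:12))
  withr::with_seed(31, {
    notes <- dplyr::bind_rows(lapply(cohort$patient_id, function(pid) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      dplyr::bind_rows(lapply(seq_len(k), function(j) {
        make_note(pid, random_note_text(), index_date - sample(0:700, 1),
                  note_id = paste0(pid, "-N", j))
      }))
    }))
    base <- classify_cohort(cohort, notes, lex, index_date)

    # duplicating every note changes nothing about the labels
    dup <- notes
    dup$note_id <- paste0(dup$note_id, "dup")
    both <- classify_cohort(cohort, dplyr::bind_rows(notes, dup), lex, index_date)
    expect_equal(both$label, base$label)

    # adding a note can never flip user -> non-user
    extra <- make_note("P01", "routine follow-up, no concerns",
                       index_date - 5, note_id = "P01-extra")
    more <- classify_cohort(cohort, dplyr::bind_rows(notes, extra), lex, index_date)
    was_user <- base$label == "preliminary_user"
    expect_true(all(more$label[was_user] == "preliminary_user"))
  })
})

test_that("classifier labels match the concatenate-and-scan oracle", {
  lex <- default_lexicon()
  terms <- enabled_terms(lex)
  withr::with_seed(77, {
    for (rep in 1:25) {
      pid <- "P1"
      k <- sample(1:4, 1)
      notes <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
        make_note(pid, random_note_text(sample(3:15, 1)),
                  index_date - sample(0:500, 1), note_id = paste0("N", j))
      }))
      got <- classify_patient(pid, notes, lex, index_date)$label
      expect_equal(got, oracle_label(notes, terms, index_date, 365L))
    }
  })
})

test_that("arm sampling draws per arm, then excludes deceased and no-contact", {
  withr::with_seed(5, {
    n_u <- 62; n_n <- 148
    ids <- sprintf("P%03d", 1:(n_u + n_n))
    cls <- tibble::tibble(
      patient_id = ids,
      label = rep(c("preliminary_user", "preliminary_nonuser"), c(n_u, n_n)))
    patients <- dplyr::bind_rows(lapply(ids, make_patient))
  })
  arms1 <- sample_arms(cls, patients, n_per_arm = 51, seed = 11)
  arms2 <- sample_arms(cls, patients, n_per_arm = 51, seed = 11)
  expect_identical(arms1[c("users", "nonusers", "excluded_deceased")],
                   arms2[c("users", "nonusers", "excluded_deceased")])
  expect_length(arms1$sampled_users, 51)
  expect_length(arms1$sampled_nonusers, 51)
  expect_length(intersect(arms1$users, arms1$nonusers), 0)

  # plant deceased on 2 sampled users + 1 sampled nonuser, no-contact on 2 more
  patients$deceased <- patients$patient_id %in%
    c(arms1$sampled_users[1:2], arms1$sampled_nonusers[1])
  noc <- c(arms1$sampled_users[3], arms1$sampled_nonusers[2])
  patients$has_contact_info <- !patients$patient_id %in% noc
  arms3 <- sample_arms(cls, patients, n_per_arm = 51, seed = 11)
  expect_length(arms3$excluded_deceased, 3)
  expect_equal(length(arms3$users) + length(arms3$nonusers) +
                 length(arms3$excluded_no_contact), 99)
  expect_length(contactable_ids(arms3), 97)
  expect_length(intersect(contactable_ids(arms3),
                          c(arms3$excluded_deceased, arms3$excluded_no_contact)), 0)

  expect_error(sample_arms(cls, patients, n_per_arm = 200, seed = 1),
               "user arm", class = "cannaphen_validation_error")
})

test_that("classifications round-trip through CSV", {
  lex <- default_lexicon()
  cls <- classify_cohort(tibble::tibble(patient_id = c("A", "B")),
                         make_note("A", "mjx noted", index_date - 3),
                         lex, index_date)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_classifications(cls, tmp, seed = 2)
  back <- read_classifications(tmp)
  expect_equal(back$patient_id, cls$patient_id)
  expect_equal(back$label, cls$label)
  expect_equal(back$n_supporting_mentions, cls$n_supporting_mentions)
  expect_equal(back$first_mention_date, cls$first_mention_date)
})
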