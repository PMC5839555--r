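test_that("simulation config validates probabilities", {
  expect_error(simulation_config(p_ever_use = 1.2),
               class = "cannaphen_validation_error")
  expect_error(simulation_config(completion_rate = -0.1),
               class = "cannaphen_validation_error")
  expect_error(simulation_config(n_patients = 0),
               class = "cannaphen_validation_error")
})

test_that("generated registries pass the cohort filters exactly as planted", {
  cfg <- simulation_config(n_patients = 80, n_noncohort = 20, seed = 12)
  study <- generate_study(cfg)
  expect_equal(nrow(study$patients), 100)
  cohort <- select_cohort(study$patients, cohort_spec())
  expect_equal(nrow(cohort), 80)
  expect_setequal(cohort$patient_id, study$truth$patient_id)
})

test_that("a fixed seed reproduces the study byte-for-byte", {
  cfg <- simulation_config(n_patients = 40, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(cfg, out_dir = d1)
  generate_study(cfg, out_dir = d2)
  for (f in c("patients.csv", "notes.jsonl", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("noiseless limit: classifier arms partition past-year users exactly", {
  cfg <- simulation_config(n_patients = 150, seed = 4,
                           p_documented_given_past_year_use = 1,
                           p_term_given_no_past_year_use = 0,
                           negated_mention_rate = 0)
  study <- generate_study(cfg)
  cls <- classify_cohort(select_cohort(study$patients, cohort_spec()),
                         study$notes, default_lexicon(),
                         cfg$index_date, cfg$lookback_days)
  merged <- merge(cls[, c("patient_id", "label")], study$truth)
  expect_true(all(merged$label[merged$past_year] == "preliminary_user"))
  expect_true(all(merged$label[!merged$past_year] == "preliminary_nonuser"))
})

test_that("confounder tokens never create mentions", {
  cfg <- simulation_config(n_patients = 120, seed = 6,
                           p_documented_given_past_year_use = 0,
                           p_term_given_no_past_year_use = 0,
                           negated_mention_rate = 0,
                           p_out_of_window_mention = 0,
                           confounder_rate = 1)
  study <- generate_study(cfg)
  expect_equal(nrow(find_mentions(study$notes, default_lexicon())), 0)
})

test_that("exact-count planting recovers every narrative count", {
  seed <- 2026
  cfg <- simulation_config(seed = seed, exact = exact_counts(sampling_seed = seed))
  study <- generate_study(cfg)
  cohort <- select_cohort(study$patients, cohort_spec())
  expect_equal(nrow(cohort), 210)
  cls <- classify_cohort(cohort, study$notes, default_lexicon(),
                         cfg$index_date, cfg$lookback_days)
  expect_equal(sum(cls$label == "preliminary_user"), 62)
  expect_equal(sum(cls$label == "preliminary_nonuser"), 148)
  arms <- sample_arms(cls, study$patients, n_per_arm = 51, seed = seed)
  expect_length(arms$excluded_deceased, 3)
  expect_length(arms$excluded_no_contact, 2)
  expect_length(contactable_ids(arms), 97)

  iv <- generate_interviews(study$truth, contactable_ids(arms), seed = seed,
                            exact = cfg$exact$interview, arms = arms)
  tab <- build_concordance(cls, iv)
  expect_equal(unname(tab$arm_totals), c(35L, 34L))
  expect_equal(unname(tab$counts[, "term_positive"]), c(15L, 17L, 2L, 33L))
  expect_equal(unname(tab$counts[, "term_negative"]), c(3L, 4L, 11L, 23L))
})

test_that("interview generator respects truth at zero noise and zero completion", {
  cfg <- simulation_config(n_patients = 60, seed = 10)
  study <- generate_study(cfg)
  iv <- generate_interviews(study$truth, completion_rate = 1,
                            misreport_rate = 0, seed = 3)
  m <- merge(iv, study$truth)
  expect_true(all(m$completed))
  expect_equal(m$used_past_30d, m$past_30d)
  expect_equal(m$used_past_year, m$past_year)
  expect_equal(m$ever_used, m$ever)

  none <- generate_interviews(study$truth, completion_rate = 0, seed = 3)
  expect_equal(sum(none$completed), 0)
})

test_that("interview flags keep the recall-window nesting after misreport flips", {
  cfg <- simulation_config(n_patients = 100, seed = 5)
  study <- generate_study(cfg)
  for (s in 1:10) {
    iv <- generate_interviews(study$truth, completion_rate = 0.8,
                              misreport_rate = 0.3, seed = s)
    expect_silent(validate_interviews(iv))
  }
})

test_that("completions follow the binomial expectation across seeds", {
  cfg <- simulation_config(n_patients = 97, seed = 1)
  study <- generate_study(cfg)
  m <- 150
  comp <- vapply(seq_len(m), function(s) {
    sum(generate_interviews(study$truth, completion_rate = 0.71,
                            seed = s)$completed)
  }, numeric(1))
  mu <- 97 * 0.71
  se <- sqrt(97 * 0.71 * 0.29 / m)
  expect_lt(abs(mean(comp) - mu), 3 * se)
})

test_that("negated mentions are detected, raising the false-positive rate monotonically", {
  fp_rate <- vapply(c(0, 0.2, 0.45), function(neg) {
    cfg <- simulation_config(n_patients = 2500, seed = 17,
                             negated_mention_rate = neg)
    study <- generate_study(cfg)
    cls <- classify_cohort(select_cohort(study$patients, cohort_spec()),
                           study$notes, default_lexicon(),
                           cfg$index_date, cfg$lookback_days)
    m <- merge(cls[, c("patient_id", "label")], study$truth)
    mean(m$label[!m$past_year] == "preliminary_user")
  }, numeric(1))
  expect_true(all(diff(fp_rate) > 0))
})

test_that("exposure generator emits records only for completed current users", {
  cfg <- simulation_config(n_patients = 200, seed = 8)
  study <- generate_study(cfg)
  iv <- generate_interviews(study$truth, completion_rate = 0.9,
                            misreport_rate = 0, seed = 8)
  ex <- generate_exposures(iv, seed = 8)
  cur <- iv$patient_id[iv$completed & iv$used_past_30d]
  expect_setequal(ex$patient_id, cur)
  expect_silent(validate_exposures(ex))
  expect_true(all(ex$joints_per_day[ex$primary_mode == "other"] == 0))
  expect_equal(nrow(generate_exposures(iv[iv$used_past_30d == FALSE, ],
                                       seed = 8)), 0)
})

test_that("exact plans are validated", {
  expect_error(exact_counts(n_term_positive = 300),
               class = "cannaphen_validation_error")
  expect_error(exact_counts(n_per_arm = 100),
               class = "cannaphen_validation_error")
  expect_error(exact_counts(interview = list(
    term_positive = list(completed = 35, past_30d = 20, past_year = 17, ever = 33),
    term_negative = list(completed = 34, past_30d = 3, past_year = 4, ever = 23))),
    class = "cannaphen_validation_error")
})
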