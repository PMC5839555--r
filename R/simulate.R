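# Synthetic EHR generator: patient registries, templated clinical notes
# with a latent truth model, interview responses and exposure records.
# Two modes: probabilistic (property tests, parameter recovery) and
# exact-count planting (reproducing published narrative counts).

#' Simulation configuration
#'
#' Parameterizes the latent truth model (nested lifetime / past-year /
#' past-30-day use), the documentation model linking true use to note
#' mentions, note volume and content noise, and downstream interview
#' behaviour. Defaults describe a cohort of patients aged 65-67 with
#' coronary artery disease seen in 2015: roughly half report lifetime
#' use, past-year use sits near 16%, and documentation plus a small
#' false-mention channel yields a term-positive fraction near 30% of the
#' cohort, with interview completion near 71%.
#'
#' @param n_patients cohort size (patients passing the registry filters).
#' @param p_ever_use probability of lifetime use.
#' @param p_past_year_given_ever probability of past-year use among ever
#'   users.
#' @param p_past_30d_given_past_year probability of past-30-day use among
#'   past-year users.
#' @param p_documented_given_past_year_use probability that a past-year
#'   user's use is documented with an in-window term mention.
#' @param p_term_given_no_past_year_use probability that a patient
#'   without past-year use nevertheless has an in-window term mention
#'   (e.g. historical-use notes).
#' @param negated_mention_rate probability (for any patient) of an
#'   additional in-window mention phrased in negation ("denies marijuana
#'   use"). Such mentions still match — the method is deliberately
#'   negation-blind — so this rate feeds the false-positive channel.
#' @param notes_per_patient Poisson mean of background (mention-free)
#'   notes per patient.
#' @param confounder_rate probability a background note carries a
#'   boundary-confuser token (TMJ, cannabinoid, ...) that must *not*
#'   match.
#' @param p_out_of_window_mention probability a patient without in-window
#'   mentions has a mention note dated before the lookback window.
#' @param p_deceased,p_no_contact registry rates of death and missing
#'   contact information (probabilistic mode).
#' @param completion_rate,misreport_rate interview completion and
#'   per-flag misreport probabilities.
#' @param n_noncohort extra registry rows that fail the cohort filters
#'   (exercises [select_cohort()]); default 15% of `n_patients`.
#' @param index_date,lookback_days classification anchor and window.
#' @param seed master seed; named sub-streams (registry, truth, notes,
#'   interviews, exposures) are derived from it so adding one generator
#'   does not perturb the others.
#' @param exact `NULL` for probabilistic mode, or an [exact_counts()]
#'   plan for exact-count planting.
#' @return a `cannaphen_sim_config` list.
#' @export
simulation_config <- function(n_patients = 210L,
                              p_ever_use = 0.55,
                              p_past_year_given_ever = 0.30,
                              p_past_30d_given_past_year = 0.80,
                              p_documented_given_past_year_use = 0.85,
                              p_term_given_no_past_year_use = 0.10,
                              negated_mention_rate = 0.05,
                              notes_per_patient = 3,
                              confounder_rate = 0.30,
                              p_out_of_window_mention = 0.15,
                              p_deceased = 0.03,
                              p_no_contact = 0.02,
                              completion_rate = 0.71,
                              misreport_rate = 0.05,
                              n_noncohort = NULL,
                              index_date = as.Date("2015-12-31"),
                              lookback_days = 365L,
                              seed = 1L,
                              exact = NULL) {
  probs <- list(p_ever_use = p_ever_use,
                p_past_year_given_ever = p_past_year_given_ever,
                p_past_30d_given_past_year = p_past_30d_given_past_year,
                p_documented_given_past_year_use = p_documented_given_past_year_use,
                p_term_given_no_past_year_use = p_term_given_no_past_year_use,
                negated_mention_rate = negated_mention_rate,
                confounder_rate = confounder_rate,
                p_out_of_window_mention = p_out_of_window_mention,
                p_deceased = p_deceased, p_no_contact = p_no_contact,
                completion_rate = completion_rate,
                misreport_rate = misreport_rate)
  for (nm in names(probs)) stop_if_not_probability(probs[[nm]], nm)
  if (n_patients < 1) {
    abort("`n_patients` must be positive.", class = "cannaphen_validation_error")
  }
  structure(c(list(n_patients = as.integer(n_patients),
                   notes_per_patient = notes_per_patient,
                   n_noncohort = as.integer(n_noncohort %||%
                                              ceiling(0.15 * n_patients)),
                   index_date = as.Date(index_date),
                   lookback_days = as.integer(lookback_days),
                   seed = as.integer(seed), exact = exact),
              probs),
            class = "cannaphen_sim_config")
}

#' Exact-count planting plan
#'
#' Describes a study whose narrative counts are planted exactly rather
#' than sampled: the cohort size, the term-positive split, the arm draw,
#' how many *sampled* patients are deceased or lack contact information,
#' and (optionally) exact interview cell counts per arm. The generator
#' replays the seeded arm draw internally so the exclusion flags land on
#' ids the draw will actually select, whatever the seed.
#'
#' @param n_cohort patients passing the cohort filters.
#' @param n_term_positive of these, patients planted with an in-window
#'   term mention.
#' @param n_per_arm patients drawn per arm.
#' @param sampling_seed seed of the arm draw (pass the same seed to
#'   [sample_arms()]).
#' @param n_deceased_users,n_deceased_nonusers sampled patients planted
#'   deceased, per arm.
#' @param n_no_contact_users,n_no_contact_nonusers surviving sampled
#'   patients planted without contact information, per arm.
#' @param interview optional per-arm interview cell plan: a list with
#'   `term_positive` and `term_negative`, each
#'   `list(completed, past_30d, past_year, ever)`.
#' @param disposition_plan optional breakdown of the contacted patients
#'   who did not complete: `list(refused_by_message, refused_on_call,
#'   unreachable)`; must account exactly for contacted minus completed.
#' @return an `exact` plan list for [simulation_config()].
#' @export
exact_counts <- function(n_cohort = 210L, n_term_positive = 62L,
                         n_per_arm = 51L, sampling_seed = 1L,
                         n_deceased_users = 2L, n_deceased_nonusers = 1L,
                         n_no_contact_users = 1L, n_no_contact_nonusers = 1L,
                         interview = list(
                           term_positive = list(completed = 35L, past_30d = 15L,
                                                past_year = 17L, ever = 33L),
                           term_negative = list(completed = 34L, past_30d = 3L,
                                                past_year = 4L, ever = 23L)),
                         disposition_plan = list(refused_by_message = 1L,
                                                 refused_on_call = 20L,
                                                 unreachable = 7L)) {
  if (n_term_positive > n_cohort) {
    abort("`n_term_positive` cannot exceed `n_cohort`.",
          class = "cannaphen_validation_error")
  }
  if (n_per_arm > n_term_positive ||
        n_per_arm > n_cohort - n_term_positive) {
    abort("`n_per_arm` exceeds an arm of the planted split.",
          class = "cannaphen_validation_error")
  }
  if (!is.null(interview)) {
    for (arm in names(interview)) {
      p <- interview[[arm]]
      if (!(p$past_30d <= p$past_year && p$past_year <= p$ever &&
              p$ever <= p$completed)) {
        abort(sprintf("Interview plan for %s violates category nesting.", arm),
              class = "cannaphen_validation_error")
      }
    }
  }
  list(n_cohort = as.integer(n_cohort),
       n_term_positive = as.integer(n_term_positive),
       n_per_arm = as.integer(n_per_arm),
       sampling_seed = as.integer(sampling_seed),
       n_deceased_users = as.integer(n_deceased_users),
       n_deceased_nonusers = as.integer(n_deceased_nonusers),
       n_no_contact_users = as.integer(n_no_contact_users),
       n_no_contact_nonusers = as.integer(n_no_contact_nonusers),
       interview = interview, disposition_plan = disposition_plan)
}

note_templates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "note_templates.yaml",
                                package = "cannaphen")
  yaml::read_yaml(path)
}

# Realistic case variation for planted terms (draws from the active RNG).
vary_case <- function(terms) {
  style <- sample.int(3L, length(terms), replace = TRUE,
                      prob = c(0.7, 0.15, 0.15))
  out <- terms
  out[style == 2L] <- toupper(terms[style == 2L])
  out[style == 3L] <- paste0(toupper(substring(terms[style == 3L], 1, 1)),
                             substring(terms[style == 3L], 2))
  out
}

fill_templates <- function(templates, n, terms = NULL) {
  txt <- sample(templates, n, replace = TRUE)
  if (!is.null(terms) && n > 0) {
    slot_terms <- vary_case(sample(terms, n, replace = TRUE))
    for (i in seq_len(n)) {
      txt[i] <- gsub("{term}", slot_terms[i], txt[i], fixed = TRUE)
    }
  }
  txt
}

random_dates <- function(n, from, to) {
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

# One qualifying registry row block (CAD code, age band, 2015-window visit)
# plus n_noncohort rows failing exactly one filter each.
simulate_registry <- function(config) {
  n <- config$n_patients
  nx <- config$n_noncohort
  total <- n + nx
  win_end <- config$index_date
  win_start <- win_end - config$lookback_days + 1L
  withr::with_seed(sub_seed(config$seed, "registry"), {
    ids <- sprintf("P%06d", seq_len(total))
    age <- sample(65:67, total, replace = TRUE)
    cad <- sprintf("%s.%02d", sample(default_cad_codes(), total, TRUE),
                   sample(0:9, total, TRUE))
    extra <- sample(c("250.00", "401.9", "715.90", "272.4", "496"),
                    total, TRUE)
    n_visits <- sample(1:3, total, replace = TRUE)
    visits <- lapply(seq_len(total), function(i) {
      sort(random_dates(n_visits[i], win_start, win_end))
    })
    deceased <- as.logical(rbinom(total, 1, config$p_deceased))
    contact <- !as.logical(rbinom(total, 1, config$p_no_contact))
    if (nx > 0) {
      # each non-cohort row fails one rotating criterion
      why <- rep_len(c("age", "dx", "visit"), nx)
      for (k in seq_len(nx)) {
        i <- n + k
        if (why[k] == "age") {
          age[i] <- sample(c(55:64, 68:80), 1)
        } else if (why[k] == "dx") {
          cad[i] <- NA_character_
        } else {
          visits[[i]] <- random_dates(n_visits[i], win_start - 400L,
                                      win_start - 36L)
        }
      }
    }
    tibble(
      patient_id = ids, age_years = as.integer(age),
      diagnosis_codes = lapply(seq_len(total), function(i) {
        codes <- c(cad[i], extra[i])
        codes[!is.na(codes)]
      }),
      visit_dates = visits,
      deceased = deceased, has_contact_info = contact
    )
  })
}

simulate_truth <- function(config, cohort_ids) {
  n <- length(cohort_ids)
  withr::with_seed(sub_seed(config$seed, "truth"), {
    ever <- as.logical(rbinom(n, 1, config$p_ever_use))
    py <- ever & as.logical(rbinom(n, 1, config$p_past_year_given_ever))
    p30 <- py & as.logical(rbinom(n, 1, config$p_past_30d_given_past_year))
    doc <- py & as.logical(rbinom(n, 1, config$p_documented_given_past_year_use))
    fp <- !py & as.logical(rbinom(n, 1, config$p_term_given_no_past_year_use))
    neg <- as.logical(rbinom(n, 1, config$negated_mention_rate))
    tibble(patient_id = cohort_ids, ever = ever, past_year = py,
           past_30d = p30, documented = doc,
           false_term = fp, negated_note = neg)
  })
}

build_notes <- function(config, cohort_ids, mention_plan) {
  tpl <- note_templates()
  terms <- enabled_terms(default_lexicon())
  win_end <- config$index_date
  win_start <- win_end - config$lookback_days + 1L
  span_start <- win_start - 365L
  withr::with_seed(sub_seed(config$seed, "notes"), {
    n <- length(cohort_ids)
    n_bg <- rpois(n, config$notes_per_patient)
    bg_pid <- rep(cohort_ids, n_bg)
    bg <- tibble(
      patient_id = bg_pid,
      note_date = random_dates(length(bg_pid), span_start, win_end),
      text = fill_templates(tpl$neutral, length(bg_pid))
    )
    conf <- as.logical(rbinom(nrow(bg), 1, config$confounder_rate))
    if (any(conf)) {
      bg$text[conf] <- paste(bg$text[conf],
                             fill_templates(tpl$confounder, sum(conf)))
    }
    planted <- lapply(names(mention_plan), function(kind) {
      ids <- mention_plan[[kind]]
      if (length(ids) == 0) return(NULL)
      templates <- switch(kind,
                          positive = tpl$positive,
                          historical = tpl$historical,
                          negated = tpl$negated,
                          out_of_window = c(tpl$positive, tpl$historical))
      dates <- if (kind == "out_of_window") {
        random_dates(length(ids), span_start, win_start - 1L)
      } else {
        random_dates(length(ids), win_start, win_end)
      }
      tibble(patient_id = ids, note_date = dates,
             text = fill_templates(templates, length(ids), terms = terms))
    })
    out <- dplyr::bind_rows(c(list(bg), planted))
    out <- out[order(match(out$patient_id, cohort_ids), out$note_date), ]
    out$note_id <- paste0(out$patient_id, "-N",
                          stats::ave(seq_len(nrow(out)), out$patient_id,
                                     FUN = seq_along))
    out[, c("patient_id", "note_id", "note_date", "text")]
  })
}

#' Generate a synthetic study
#'
#' Emits a patient registry (qualifying cohort plus filter-failing
#' rows), a templated clinical-note corpus whose in-window term mentions
#' follow the documentation model, and the latent truth table. In
#' probabilistic mode a past-year user carries an in-window mention with
#' probability `1 - (1 - p_doc)(1 - negated_rate)` and other patients
#' with probability `1 - (1 - p_term)(1 - negated_rate)`; in exact-count
#' mode the requested split is planted exactly and exclusion flags are
#' placed on ids the seeded arm draw will select. Fully reproducible
#' from the config seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, `patients.csv`,
#'   `notes.jsonl` and `truth.csv` are written there.
#' @return a list with tibbles `patients`, `notes`, `truth`, plus the
#'   `config`.
#' @export
generate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cannaphen_sim_config"))
  if (is.null(config$exact)) {
    study <- generate_study_probabilistic(config)
  } else {
    study <- generate_study_exact(config)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_patients(study$patients, file.path(out_dir, "patients.csv"),
                   seed = config$seed)
    write_notes(study$notes, file.path(out_dir, "notes.jsonl"),
                seed = config$seed)
    truth_flat <- study$truth
    write_csv_with_header(truth_flat, file.path(out_dir, "truth.csv"),
                          seed = config$seed)
  }
  study
}

generate_study_probabilistic <- function(config) {
  patients <- simulate_registry(config)
  cohort_ids <- patients$patient_id[seq_len(config$n_patients)]
  truth <- simulate_truth(config, cohort_ids)
  has_mention <- truth$documented | truth$false_term | truth$negated_note
  oow <- withr::with_seed(sub_seed(config$seed, "out_of_window"), {
    truth$patient_id[!has_mention &
                       as.logical(rbinom(nrow(truth), 1,
                                         config$p_out_of_window_mention))]
  })
  plan <- list(
    positive = truth$patient_id[truth$documented],
    historical = truth$patient_id[truth$false_term],
    negated = truth$patient_id[truth$negated_note],
    out_of_window = oow
  )
  notes <- build_notes(config, cohort_ids, plan)
  list(patients = patients, notes = notes,
       truth = truth[, c("patient_id", "ever", "past_year", "past_30d",
                         "documented")],
       config = config)
}

generate_study_exact <- function(config) {
  ex <- config$exact
  config$n_patients <- ex$n_cohort
  patients <- simulate_registry(config)
  cohort_ids <- patients$patient_id[seq_len(ex$n_cohort)]
  pos_ids <- withr::with_seed(sub_seed(config$seed, "plant"), {
    sort(sample(cohort_ids, ex$n_term_positive))
  })
  neg_ids <- setdiff(cohort_ids, pos_ids)
  truth <- withr::with_seed(sub_seed(config$seed, "truth"), {
    p30 <- as.logical(rbinom(length(pos_ids), 1,
                             config$p_past_30d_given_past_year))
    neg_ever <- as.logical(rbinom(length(neg_ids), 1, config$p_ever_use))
    dplyr::bind_rows(
      tibble(patient_id = pos_ids, ever = TRUE, past_year = TRUE,
             past_30d = p30, documented = TRUE),
      tibble(patient_id = neg_ids, ever = neg_ever, past_year = FALSE,
             past_30d = FALSE, documented = FALSE)
    )
  })
  truth <- truth[match(cohort_ids, truth$patient_id), ]
  oow <- withr::with_seed(sub_seed(config$seed, "out_of_window"), {
    neg_ids[as.logical(rbinom(length(neg_ids), 1,
                              config$p_out_of_window_mention))]
  })
  notes <- build_notes(config, cohort_ids,
                       list(positive = pos_ids, out_of_window = oow))
  # replay the seeded arm draw so exclusions land on sampled ids
  drawn <- draw_arm_ids(pos_ids[pos_ids %in% cohort_ids],
                        neg_ids, ex$n_per_arm, ex$sampling_seed)
  dec <- c(head(drawn$users, ex$n_deceased_users),
           head(drawn$nonusers, ex$n_deceased_nonusers))
  noc <- c(head(setdiff(drawn$users, dec), ex$n_no_contact_users),
           head(setdiff(drawn$nonusers, dec), ex$n_no_contact_nonusers))
  patients$deceased <- patients$patient_id %in% dec
  patients$has_contact_info <- !(patients$patient_id %in% noc)
  list(patients = patients, notes = notes, truth = truth, config = config)
}

#' Generate interview responses
#'
#' In probabilistic mode each subject completes the interview with
#' probability `completion_rate`; completed responses equal the latent
#' truth with each flag independently flipped with probability
#' `misreport_rate`, after which the recall-window nesting
#' (past 30 days => past year => ever) is re-imposed. With an exact plan
#' the per-arm completed totals and nested category counts are planted
#' exactly. Baseline covariates (tobacco status, weekly exercise METs,
#' heavy drinking, depression screen) are simulated conditionally on
#' current use.
#'
#' @param truth a truth tibble from [generate_study()].
#' @param subject_ids patients to interview (default: all of `truth`;
#'   typically [contactable_ids()] of the arm sample).
#' @param completion_rate,misreport_rate response model probabilities.
#' @param seed integer seed.
#' @param exact optional exact plan (the `interview` element of
#'   [exact_counts()]); requires `arms`.
#' @param arms a `cannaphen_arm_sample`, required with `exact`.
#' @return an interview tibble with response flags and covariates.
#' @export
generate_interviews <- function(truth, subject_ids = NULL,
                                completion_rate = 0.71,
                                misreport_rate = 0.05,
                                seed = 1L, exact = NULL, arms = NULL) {
  stop_if_not_probability(completion_rate, "completion_rate")
  stop_if_not_probability(misreport_rate, "misreport_rate")
  subject_ids <- subject_ids %||% truth$patient_id
  if (is.null(exact)) {
    t <- truth[match(subject_ids, truth$patient_id), ]
    out <- withr::with_seed(sub_seed(seed, "interviews"), {
      n <- length(subject_ids)
      completed <- as.logical(rbinom(n, 1, completion_rate))
      flip <- function(x) xor(x, as.logical(rbinom(n, 1, misreport_rate)))
      p30 <- flip(t$past_30d); py <- flip(t$past_year); ever <- flip(t$ever)
      py <- py | p30          # re-impose nesting after flips
      ever <- ever | py
      tibble(patient_id = subject_ids, completed = completed,
             used_past_30d = completed & p30,
             used_past_year = completed & py,
             ever_used = completed & ever)
    })
  } else {
    if (is.null(arms)) {
      abort("Exact interview planting needs the arm sample (`arms`).",
            class = "cannaphen_validation_error")
    }
    out <- withr::with_seed(sub_seed(seed, "interviews"), {
      plant_arm <- function(ids, plan) {
        if (length(ids) < plan$completed) {
          abort("Arm smaller than planted completed count.",
                class = "cannaphen_validation_error")
        }
        ids <- sample(ids)   # random order, then assign nested categories
        done <- head(ids, plan$completed)
        k30 <- plan$past_30d
        kpy <- plan$past_year
        kev <- plan$ever
        tibble(
          patient_id = ids,
          completed = ids %in% done,
          used_past_30d = ids %in% head(done, k30),
          used_past_year = ids %in% head(done, kpy),
          ever_used = ids %in% head(done, kev)
        )
      }
      dplyr::bind_rows(plant_arm(arms$users, exact$term_positive),
                       plant_arm(arms$nonusers, exact$term_negative))
    })
  }
  covars <- withr::with_seed(sub_seed(seed, "covariates"), {
    n <- nrow(out)
    cur <- out$used_past_30d
    tobacco <- vapply(cur, function(u) {
      sample(c("current", "former", "never"), 1,
             prob = if (u) c(0.33, 0.5, 0.17) else c(0.18, 0.58, 0.24))
    }, "")
    tibble(
      tobacco_status = tobacco,
      weekly_mets = round(stats::rgamma(n, shape = 2,
                                        rate = ifelse(cur, 0.24, 0.16)), 1),
      heavy_drinking = as.logical(rbinom(n, 1, ifelse(cur, 0.28, 0.18))),
      positive_depression_screen =
        as.logical(rbinom(n, 1, ifelse(cur, 0.33, 0.24)))
    )
  })
  dplyr::bind_cols(out, covars)
}

#' Generate exposure records for current users
#'
#' One record per completed interview reporting past-30-day use:
#' predominant mode (smoked ~89%), smoking frequency category,
#' joints/day, days of use in the past year (from
#' [frequency_days_map()]) and any other modes used. Non-smoking
#' predominant users get zero joints/day.
#'
#' @param interviews an interview tibble.
#' @param seed integer seed.
#' @return a validated exposure tibble (possibly zero rows).
#' @export
generate_exposures <- function(interviews, seed = 1L) {
  cur <- interviews[interviews$completed & interviews$used_past_30d, ,
                    drop = FALSE]
  days_map <- frequency_days_map()
  if (nrow(cur) == 0) {
    return(tibble(patient_id = character(), primary_mode = character(),
                  frequency_category = character(),
                  joints_per_day = numeric(),
                  days_used_past_year = integer(), other_modes = list()))
  }
  out <- withr::with_seed(sub_seed(seed, "exposures"), {
    n <- nrow(cur)
    mode <- ifelse(rbinom(n, 1, 0.89) == 1, "smoked", "other")
    freq <- vapply(seq_len(n), function(i) {
      sample(c("daily", "weekly_not_daily", "two_three_per_month",
               "less_often"), 1, prob = c(0.39, 0.11, 0.06, 0.44))
    }, "")
    jpd <- ifelse(mode == "smoked",
                  sample(c(0.5, 1, 1.5, 2, 3), n, replace = TRUE,
                         prob = c(0.3, 0.35, 0.15, 0.15, 0.05)),
                  0)
    other <- lapply(seq_len(n), function(i) {
      if (mode[i] == "other") {
        sample(other_mode_levels, sample(1:2, 1))
      } else if (rbinom(1, 1, 0.55) == 1) {
        sample(other_mode_levels, sample(1:2, 1))
      } else {
        character(0)
      }
    })
    tibble(patient_id = cur$patient_id, primary_mode = mode,
           frequency_category = freq, joints_per_day = jpd,
           days_used_past_year = as.integer(days_map[freq]),
           other_modes = other)
  })
  validate_exposures(out)
  out
}

#' Analytic mention and predictive-value probabilities
#'
#' Closed-form quantities implied by a probabilistic
#' [simulation_config()]: the chance of at least one in-window mention
#' for past-year users and for others, and the Bayes-rule positive
#' predictive value `P(past-year use | >= 1 in-window mention)` that a
#' large simulated cohort's measured PPV converges to.
#'
#' @param config a probabilistic `cannaphen_sim_config`.
#' @return a list: `p_mention_given_past_year`,
#'   `p_mention_given_no_past_year`, `p_past_year`,
#'   `ppv_past_year`.
#' @export
analytic_mention_model <- function(config) {
  stopifnot(inherits(config, "cannaphen_sim_config"))
  p_py <- config$p_ever_use * config$p_past_year_given_ever
  pm1 <- 1 - (1 - config$p_documented_given_past_year_use) *
    (1 - config$negated_mention_rate)
  pm0 <- 1 - (1 - config$p_term_given_no_past_year_use) *
    (1 - config$negated_mention_rate)
  list(p_mention_given_past_year = pm1,
       p_mention_given_no_past_year = pm0,
       p_past_year = p_py,
       ppv_past_year = p_py * pm1 / (p_py * pm1 + (1 - p_py) * pm0))
}
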