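# End-to-end orchestration: simulate/load -> cohort -> classify -> sample
# -> interview concordance -> exposure -> report.

#' Pipeline configuration
#'
#' Either a simulation config (`sim`) or input paths (`notes_path`,
#' `patients_path`, and optionally `interviews_path`, `exposures_path`)
#' must be supplied. All stage artifacts are written under `out_dir`
#' with provenance headers.
#'
#' @param out_dir directory for stage artifacts (created if needed).
#' @param seed master seed; drives simulation, arm sampling and
#'   interview generation.
#' @param sim optional [simulation_config()]; when present the study is
#'   simulated rather than read from disk.
#' @param notes_path,patients_path,interviews_path,exposures_path input
#'   files used when `sim` is `NULL` (interviews/exposures are simulated
#'   from latent truth only in simulation mode, so with real inputs the
#'   interview file is required for the validation stage).
#' @param lexicon a `cannaphen_lexicon` (default [default_lexicon()]).
#' @param index_date,lookback_days classification anchor and window.
#' @param n_per_arm patients drawn per arm.
#' @param cad_codes diagnosis filter passed to [cohort_spec()].
#' @return a `cannaphen_run_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL,
                            notes_path = NULL, patients_path = NULL,
                            interviews_path = NULL, exposures_path = NULL,
                            lexicon = default_lexicon(),
                            index_date = as.Date("2015-12-31"),
                            lookback_days = 365L, n_per_arm = 51L,
                            cad_codes = default_cad_codes()) {
  if (is.null(sim)) {
    for (p in c(notes_path, patients_path)) {
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("Input path missing or nonexistent: %s",
                      p %||% "(not given)"),
              class = "cannaphen_config_error")
      }
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 notes_path = notes_path, patients_path = patients_path,
                 interviews_path = interviews_path,
                 exposures_path = exposures_path,
                 lexicon = lexicon, index_date = as.Date(index_date),
                 lookback_days = as.integer(lookback_days),
                 n_per_arm = as.integer(n_per_arm), cad_codes = cad_codes),
            class = "cannaphen_run_config")
}

#' Packaged demo configuration
#'
#' An exact-count study: 210 cohort patients, 62 planted term-positive,
#' a 51 + 51 arm draw with 3 sampled patients deceased and 2 without
#' contact information, and interview cells planted at 15/17/33 of 35
#' and 3/4/23 of 34 — so a full run narrates the reference accounting
#' end to end.
#'
#' @param out_dir directory for artifacts.
#' @param seed master seed (also the arm-draw seed).
#' @return a `cannaphen_run_config`.
#' @export
demo_config <- function(out_dir = tempfile("cannaphen_demo_"), seed = 1L) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    sim = simulation_config(seed = seed,
                            exact = exact_counts(sampling_seed = seed))
  )
}

#' Run the full phenotyping pipeline
#'
#' Stages: obtain inputs (simulate or read), select the cohort, classify
#' by in-window term mentions, draw and prune the study arms, account
#' recruitment, cross-tabulate against interviews, compute predictive
#' values / enrichment / the ever-use association test, and summarize
#' exposure. Artifacts (`patients.csv`, `notes.jsonl`,
#' `classifications.csv`, `arms.json`, `interviews.csv`,
#' `exposures.csv`, `table1.csv`, `report.txt`) are written under
#' `config$out_dir`; any stage failure aborts with the stage name while
#' earlier artifacts are retained for debugging.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a `cannaphen_report` (list of stage results plus formatted
#'   report lines).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "cannaphen_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "cannaphen_pipeline_error")
    })
  }
  exact <- if (!is.null(config$sim)) config$sim$exact else NULL

  inputs <- stage("inputs", {
    if (!is.null(config$sim)) {
      generate_study(config$sim, out_dir = config$out_dir)
    } else {
      list(patients = read_patients(config$patients_path),
           notes = read_notes(config$notes_path), truth = NULL)
    }
  })
  say("inputs: %d registry rows, %d notes",
      nrow(inputs$patients), nrow(inputs$notes))

  spec <- cohort_spec(cad_codes = config$cad_codes,
                      visit_window_start =
                        config$index_date - config$lookback_days + 1L,
                      visit_window_end = config$index_date)
  cohort <- stage("cohort", select_cohort(inputs$patients, spec))
  say("cohort: %d patients retained", nrow(cohort))

  classifications <- stage("classify", classify_cohort(
    cohort, inputs$notes, config$lexicon,
    config$index_date, config$lookback_days))
  n_users <- sum(classifications$label == "preliminary_user")
  say("classification: %d preliminary users / %d preliminary non-users",
      n_users, nrow(classifications) - n_users)
  write_classifications(classifications,
                        file.path(config$out_dir, "classifications.csv"),
                        seed = config$seed)

  sampling_seed <- if (!is.null(exact)) exact$sampling_seed else config$seed
  arms <- stage("sample", sample_arms(classifications, inputs$patients,
                                      n_per_arm = config$n_per_arm,
                                      seed = sampling_seed))
  say("arms: %d + %d drawn; %d deceased; %d without contact; %d contactable",
      length(arms$sampled_users), length(arms$sampled_nonusers),
      length(arms$excluded_deceased), length(arms$excluded_no_contact),
      length(contactable_ids(arms)))
  jsonlite::write_json(
    c(list(provenance = provenance_header(config$seed)),
      lapply(unclass(arms), identity)),
    file.path(config$out_dir, "arms.json"), auto_unbox = TRUE, digits = NA)

  interviews <- stage("interviews", {
    if (!is.null(config$sim)) {
      iv <- generate_interviews(
        inputs$truth, subject_ids = contactable_ids(arms),
        completion_rate = config$sim$completion_rate,
        misreport_rate = config$sim$misreport_rate,
        seed = config$seed,
        exact = if (!is.null(exact)) exact$interview else NULL,
        arms = arms)
      write_interviews(iv, file.path(config$out_dir, "interviews.csv"),
                       seed = config$seed)
      iv
    } else if (!is.null(config$interviews_path)) {
      read_interviews(config$interviews_path)
    } else {
      NULL
    }
  })

  validation <- NULL
  dispo <- NULL
  if (!is.null(interviews)) {
    dispo <- stage("disposition", {
      reached <- interviews$patient_id %in% contactable_ids(arms)
      contacted <- sum(reached)
      completed <- sum(interviews$completed & reached)
      not_done <- contacted - completed
      split3 <- if (!is.null(exact) && !is.null(exact$disposition_plan)) {
        unlist(exact$disposition_plan)
      } else {
        withr::with_seed(sub_seed(config$seed, "disposition"), {
          as.vector(stats::rmultinom(1, not_done, prob = c(0.05, 0.7, 0.25)))
        }) |> setNames(c("refused_by_message", "refused_on_call",
                         "unreachable"))
      }
      if (sum(split3) != not_done) {
        abort("Disposition plan does not account for all non-completers.",
              class = "cannaphen_validation_error")
      }
      disposition(contacted, completed, split3[["refused_by_message"]],
                  split3[["refused_on_call"]], split3[["unreachable"]])
    })
    validation <- stage("validate", {
      tab <- build_concordance(classifications, interviews)
      write_concordance(tab, file.path(config$out_dir, "table1.csv"),
                        seed = config$seed)
      ever_cells <- c(a = tab$counts["ever", "term_positive"],
                      b = tab$counts["nonuse", "term_positive"],
                      c = tab$counts["ever", "term_negative"],
                      d = tab$counts["nonuse", "term_negative"])
      list(
        concordance = tab,
        ppv = sapply(concordance_categories, function(cc) {
          predictive_value(tab, "term_positive", cc)
        }),
        npv_arm = sapply(concordance_categories, function(cc) {
          predictive_value(tab, "term_negative", cc)
        }),
        enrichment_past_30d = enrichment(tab, "past_30d"),
        enrichment_ever = enrichment(tab, "ever"),
        ever_use_test = association_test(ever_cells["a"], ever_cells["b"],
                                         ever_cells["c"], ever_cells["d"],
                                         method = "fisher_exact")
      )
    })
    say("validation: PPV past-month %.1f%%; ever-use enrichment %.1f%% -> %.1f%%",
        validation$ppv["past_30d"], validation$enrichment_ever[1],
        validation$enrichment_ever[2])
  }

  exposure <- NULL
  if (!is.null(interviews)) {
    exposure <- stage("exposure", {
      records <- if (!is.null(config$sim)) {
        generate_exposures(interviews, seed = config$seed)
      } else if (!is.null(config$exposures_path)) {
        read_exposures(config$exposures_path)
      } else {
        NULL
      }
      if (is.null(records)) NULL else {
        write_exposures(records, file.path(config$out_dir, "exposures.csv"),
                        seed = config$seed)
        smokers <- records[records$primary_mode == "smoked", , drop = FALSE]
        list(records = records,
             pattern = if (nrow(records)) use_pattern_summary(records),
             mean_joint_years_smokers =
               if (nrow(smokers)) mean_joint_years(smokers) else NA_real_)
      }
    })
  }

  covariate_summary <- if (!is.null(interviews)) {
    done <- interviews[interviews$completed, , drop = FALSE]
    group_summary(done, grouping = "used_past_30d",
                  covariates = intersect(
                    c("tobacco_status", "weekly_mets", "heavy_drinking",
                      "positive_depression_screen"), names(done)))
  }

  report <- structure(list(
    config = config, cohort_n = nrow(cohort),
    classifications = classifications, n_users = n_users,
    n_nonusers = nrow(classifications) - n_users,
    arms = arms, disposition = dispo, interviews = interviews,
    validation = validation, exposure = exposure,
    covariate_summary = covariate_summary
  ), class = "cannaphen_report")
  report$lines <- format_report(report)
  writeLines(report$lines, file.path(config$out_dir, "report.txt"))
  say("report written to %s", file.path(config$out_dir, "report.txt"))
  report
}

format_report <- function(r) {
  cfg <- r$config
  lines <- c(
    provenance_header(cfg$seed,
                      config_hash(list(index_date = format(cfg$index_date),
                                       lookback_days = cfg$lookback_days,
                                       n_per_arm = cfg$n_per_arm,
                                       seed = cfg$seed))),
    sprintf("Generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "",
    "== Cohort and preliminary classification ==",
    sprintf("Cohort: %d patients (diagnosis + age band + visit in window).",
            r$cohort_n),
    sprintf("Lookback: %d days ending %s.", cfg$lookback_days,
            format(cfg$index_date)),
    sprintf("Preliminary users: %d; preliminary non-users: %d.",
            r$n_users, r$n_nonusers),
    "",
    "== Arm sampling ==",
    sprintf("Drew %d per arm (seed %d).", r$arms$n_per_arm, r$arms$seed),
    sprintf("Deceased removed: %d, leaving %d.",
            length(r$arms$excluded_deceased),
            length(r$arms$sampled_users) + length(r$arms$sampled_nonusers) -
              length(r$arms$excluded_deceased)),
    sprintf("Without contact information: %d, leaving %d contactable (%d users, %d non-users).",
            length(r$arms$excluded_no_contact),
            length(contactable_ids(r$arms)),
            length(r$arms$users), length(r$arms$nonusers))
  )
  if (!is.null(r$disposition)) {
    d <- r$disposition
    lines <- c(lines, "", "== Recruitment ==",
               sprintf("Contacted %d: completed %d, refused by message %d, refused on call %d, unreachable %d.",
                       d$contacted, d$completed, d$refused_by_message,
                       d$refused_on_call, d$unreachable),
               sprintf("Recruitment rate: %d%%.", recruitment_rate(d)))
  }
  if (!is.null(r$validation)) {
    v <- r$validation
    tab <- v$concordance
    cell <- function(cc, arm) {
      sprintf("%d (%s%%)", tab$counts[cc, arm],
              fmt_pct(100 * tab$counts[cc, arm] / tab$arm_totals[arm]))
    }
    lines <- c(
      lines, "", "== Concordance: text search vs interview ==",
      sprintf("%-38s %-22s %s", "",
              sprintf("Term in notes (n=%d)", tab$arm_totals["term_positive"]),
              sprintf("No term (n=%d)", tab$arm_totals["term_negative"])),
      sprintf("%-38s %-22s %s", "Self-reported use in the past month",
              cell("past_30d", "term_positive"), cell("past_30d", "term_negative")),
      sprintf("%-38s %-22s %s", "Self-reported use in past year",
              cell("past_year", "term_positive"), cell("past_year", "term_negative")),
      sprintf("%-38s %-22s %s", "Self-reported non-use (never)",
              cell("nonuse", "term_positive"), cell("nonuse", "term_negative")),
      sprintf("%-38s %-22s %s", "Ever use",
              cell("ever", "term_positive"), cell("ever", "term_negative")),
      "",
      sprintf("PPV vs past-month use: %.1f%%; vs past-year use: %.1f%%; vs lifetime use: %.1f%%.",
              v$ppv["past_30d"], v$ppv["past_year"], v$ppv["ever"]),
      sprintf("Past-month use enrichment: %.1f%% -> %.1f%% with keywords present.",
              v$enrichment_past_30d["term_negative"],
              v$enrichment_past_30d["term_positive"]),
      sprintf("Ever-use enrichment: %.1f%% -> %.1f%%.",
              v$enrichment_ever["term_negative"],
              v$enrichment_ever["term_positive"]),
      sprintf("Ever-use association (Fisher exact, two-sided): OR %.2f, p = %.4g.",
              v$ever_use_test$estimate, v$ever_use_test$p_value)
    )
  }
  if (!is.null(r$exposure) && !is.null(r$exposure$pattern)) {
    p <- r$exposure$pattern
    lines <- c(
      lines, "", "== Exposure among current users ==",
      sprintf("Current (past-30-day) users interviewed: %d.",
              nrow(r$exposure$records)),
      sprintf("Predominantly smoked: %.1f%%; daily %.1f%%, weekly-not-daily %.1f%%, 2-3/month %.1f%%, less often %.1f%%.",
              p$mode$pct[p$mode$primary_mode == "smoked"],
              p$frequency$pct[p$frequency$frequency_category == "daily"],
              p$frequency$pct[p$frequency$frequency_category == "weekly_not_daily"],
              p$frequency$pct[p$frequency$frequency_category == "two_three_per_month"],
              p$frequency$pct[p$frequency$frequency_category == "less_often"]),
      sprintf("Mean joint-years among smokers (past year): %.2f.",
              r$exposure$mean_joint_years_smokers)
    )
  }
  lines
}

#' @export
print.cannaphen_report <- function(x, ...) {
  writeLines(x$lines)
  invisible(x)
}
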