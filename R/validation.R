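# Validation statistics: recruitment accounting, the concordance table,
# predictive values, enrichment, association tests, group summaries.

#' Recruitment disposition accounting
#'
#' Per-patient outcomes of the contact attempts. The four outcome counts
#' must sum exactly to the number contacted.
#'
#' @param contacted patients called.
#' @param completed interviews completed.
#' @param refused_by_message declined by leaving a message.
#' @param refused_on_call declined during the call.
#' @param unreachable never reached.
#' @return a `cannaphen_disposition`.
#' @export
#' @examples
#' d <- disposition(contacted = 97, completed = 69, refused_by_message = 1,
#'                  refused_on_call = 20, unreachable = 7)
#' recruitment_rate(d) # 71
disposition <- function(contacted, completed, refused_by_message,
                        refused_on_call, unreachable) {
  vals <- c(contacted = contacted, completed = completed,
            refused_by_message = refused_by_message,
            refused_on_call = refused_on_call, unreachable = unreachable)
  if (any(vals < 0) || any(vals != floor(vals))) {
    abort("Disposition counts must be non-negative integers.",
          class = "cannaphen_validation_error")
  }
  if (completed + refused_by_message + refused_on_call + unreachable !=
        contacted) {
    abort("Disposition outcomes must sum to the number contacted.",
          class = "cannaphen_validation_error")
  }
  structure(as.list(as.integer(vals)) |> setNames(names(vals)),
            class = "cannaphen_disposition")
}

#' @export
print.cannaphen_disposition <- function(x, ...) {
  cat("<cannaphen_disposition>\n")
  cat(sprintf("  contacted %d: completed %d, refused by message %d, refused on call %d, unreachable %d\n",
              x$contacted, x$completed, x$refused_by_message,
              x$refused_on_call, x$unreachable))
  cat(sprintf("  recruitment rate: %d%%\n", recruitment_rate(x)))
  invisible(x)
}

#' Recruitment rate
#'
#' `100 * completed / contacted`, displayed as an integer percentage
#' (rounded half-up).
#'
#' @param d a [disposition()].
#' @return integer percentage.
#' @export
recruitment_rate <- function(d) {
  stopifnot(inherits(d, "cannaphen_disposition"))
  if (d$contacted == 0) {
    abort("Recruitment rate undefined: nobody contacted.",
          class = "cannaphen_undefined_rate_error")
  }
  as.integer(round_half_up(100 * d$completed / d$contacted, 0))
}

concordance_categories <- c("past_30d", "past_year", "nonuse", "ever")
concordance_arms <- c("term_positive", "term_negative")

#' Construct a concordance table from cell counts
#'
#' The table cross-tabulates the text-search arm (term in notes in the
#' past year vs no term) against overlapping self-report categories: use
#' in the past 30 days, use in the past year, lifetime never-use
#' (`nonuse`), and lifetime ever-use. The categories nest
#' (past 30 days <= past year <= ever) and `nonuse` is the complement of
#' `ever` within the arm, so the rows are *not* a partition and columns
#' do not sum to the arm total.
#'
#' @param counts a 4 x 2 matrix (or object coercible to one) with rows
#'   `past_30d`, `past_year`, `nonuse`, `ever` and columns
#'   `term_positive`, `term_negative`.
#' @param arm_totals named integer vector with the number of completed
#'   interviews per arm.
#' @return a `cannaphen_concordance`.
#' @export
#' @examples
#' concordance_table(
#'   counts = rbind(past_30d = c(15, 3), past_year = c(17, 4),
#'                  nonuse = c(2, 11), ever = c(33, 23)),
#'   arm_totals = c(term_positive = 35, term_negative = 34))
concordance_table <- function(counts, arm_totals) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- concordance_categories
  if (is.null(colnames(counts))) colnames(counts) <- concordance_arms
  counts <- counts[concordance_categories, concordance_arms, drop = FALSE]
  storage.mode(counts) <- "integer"
  arm_totals <- setNames(as.integer(arm_totals[concordance_arms]),
                         concordance_arms)
  if (any(counts < 0) || any(arm_totals < 0)) {
    abort("Concordance counts must be non-negative.",
          class = "cannaphen_validation_error")
  }
  for (arm in concordance_arms) {
    k <- counts[, arm]
    if (!(k["past_30d"] <= k["past_year"] && k["past_year"] <= k["ever"])) {
      abort(sprintf("Nesting violated in %s arm: need past_30d <= past_year <= ever.",
                    arm),
            class = "cannaphen_validation_error")
    }
    if (k["ever"] + k["nonuse"] != arm_totals[arm]) {
      abort(sprintf("In %s arm, ever (%d) + never (%d) must equal the arm total (%d).",
                    arm, k["ever"], k["nonuse"], arm_totals[arm]),
            class = "cannaphen_validation_error")
    }
  }
  structure(list(counts = counts, arm_totals = arm_totals),
            class = "cannaphen_concordance")
}

#' Cross-tabulate classifications against interview self-report
#'
#' Builds the concordance table from completed interviews only. Every
#' completed interview must have a classification; ids lacking one raise
#' an error listing them. `nonuse` counts completed interviews reporting
#' no lifetime use.
#'
#' @param classifications a classification tibble.
#' @param interviews an interview tibble (see [read_interviews()]).
#' @return a `cannaphen_concordance`.
#' @export
build_concordance <- function(classifications, interviews) {
  validate_interviews(interviews)
  done <- interviews[interviews$completed, , drop = FALSE]
  idx <- match(done$patient_id, classifications$patient_id)
  if (anyNA(idx)) {
    abort(sprintf("Interview without classification for: %s",
                  paste(done$patient_id[is.na(idx)], collapse = ", ")),
          class = "cannaphen_validation_error")
  }
  arm <- ifelse(classifications$label[idx] == "preliminary_user",
                "term_positive", "term_negative")
  counts <- sapply(concordance_arms, function(a) {
    g <- done[arm == a, , drop = FALSE]
    c(past_30d = sum(g$used_past_30d),
      past_year = sum(g$used_past_year),
      nonuse = sum(!g$ever_used),
      ever = sum(g$ever_used))
  })
  concordance_table(counts,
                    arm_totals = setNames(as.integer(table(factor(
                      arm, levels = concordance_arms))), concordance_arms))
}

#' @export
print.cannaphen_concordance <- function(x, ...) {
  cat("<cannaphen_concordance>  completed interviews:",
      sprintf("term-positive n=%d, term-negative n=%d\n",
              x$arm_totals["term_positive"], x$arm_totals["term_negative"]))
  lab <- c(past_30d = "Self-reported use in the past month",
           past_year = "Self-reported use in past year",
           nonuse = "Self-reported non-use (never)",
           ever = "Ever use")
  for (cat_ in concordance_categories) {
    cells <- vapply(concordance_arms, function(a) {
      sprintf("%d (%s%%)", x$counts[cat_, a],
              fmt_pct(100 * x$counts[cat_, a] / x$arm_totals[a]))
    }, "")
    cat(sprintf("  %-38s %-12s %-12s\n", lab[cat_], cells[1], cells[2]))
  }
  invisible(x)
}

#' Predictive value of the text-search classification
#'
#' The proportion of an arm's completed interviews falling in a
#' self-report category, as a percentage rounded half-up to one decimal.
#' For the term-positive arm this is the positive predictive value
#' against the chosen reference standard (past-month, past-year, or
#' lifetime use).
#'
#' @param table a `cannaphen_concordance`.
#' @param arm `"term_positive"` or `"term_negative"`.
#' @param category one of `"past_30d"`, `"past_year"`, `"nonuse"`,
#'   `"ever"`.
#' @return percentage in \[0, 100\], one decimal.
#' @export
predictive_value <- function(table, arm = concordance_arms,
                             category = concordance_categories) {
  stopifnot(inherits(table, "cannaphen_concordance"))
  arm <- match.arg(arm)
  category <- match.arg(category)
  total <- table$arm_totals[[arm]]
  if (total == 0) {
    abort(sprintf("Predictive value undefined: %s arm total is zero.", arm),
          class = "cannaphen_undefined_rate_error")
  }
  round_half_up(100 * table$counts[category, arm] / total, 1)
}

#' Enrichment of a self-report category by the text search
#'
#' The pair of arm rates for a category, term-negative arm first, so the
#' natural reading is "prevalence increased from x% to y% in patients
#' with the keywords in their record".
#'
#' @inheritParams predictive_value
#' @return named numeric of length 2: `term_negative`, `term_positive`.
#' @export
enrichment <- function(table, category = concordance_categories) {
  category <- match.arg(category)
  c(term_negative = predictive_value(table, "term_negative", category),
    term_positive = predictive_value(table, "term_positive", category))
}

#' Association test for a 2 x 2 table
#'
#' Tests independence of rows and columns of the table
#' `rbind(c(a, b), c(c, d))`. `fisher_exact` (the default reported test;
#' cells here are small) returns the two-sided p from the hypergeometric
#' distribution and the conditional odds-ratio estimate; the chi-square
#' variants return the Pearson statistic, without (`chi2`) or with
#' (`chi2_yates`) continuity correction, and its p on 1 df.
#'
#' @param a,b,c,d non-negative cell counts, row-wise.
#' @param method `"fisher_exact"`, `"chi2"`, or `"chi2_yates"`.
#' @return a list with `method`, `p_value`, and `estimate` (odds ratio)
#'   or `statistic` (chi-square).
#' @export
#' @examples
#' association_test(33, 2, 23, 11)$p_value
association_test <- function(a, b, c, d,
                             method = c("fisher_exact", "chi2", "chi2_yates")) {
  method <- match.arg(method)
  m <- matrix(c(a, c, b, d), nrow = 2)
  if (any(m < 0) || any(m != floor(m))) {
    abort("Cell counts must be non-negative integers.",
          class = "cannaphen_validation_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate 2x2 table: a row or column margin is zero.",
          class = "cannaphen_validation_error")
  }
  if (method == "fisher_exact") {
    ft <- stats::fisher.test(m, alternative = "two.sided")
    list(method = method, estimate = unname(ft$estimate),
         p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(
      stats::chisq.test(m, correct = (method == "chi2_yates")))
    list(method = method, statistic = unname(ct$statistic),
         p_value = ct$p.value)
  }
}

#' Per-group descriptive summaries
#'
#' Baseline-characteristics style summaries: for each covariate column,
#' the percentage (binary or categorical covariates) or mean (numeric)
#' within each level of a grouping flag. Purely descriptive — no
#' hypothesis tests are attached.
#'
#' @param data a tibble containing `grouping` and covariate columns.
#' @param grouping name of a logical column splitting the groups
#'   (e.g. current-use flag).
#' @param covariates covariate column names; default: every column other
#'   than `grouping` and `patient_id`.
#' @return a tibble with `group`, `variable`, `level`, `n`, `stat`
#'   (`"mean"` or `"pct"`), `value`. Percentages are rounded half-up to
#'   one decimal. Empty groups yield `NA` values with a warning.
#' @export
group_summary <- function(data, grouping, covariates = NULL) {
  if (!grouping %in% names(data)) {
    abort(sprintf("Grouping column `%s` not found.", grouping),
          class = "cannaphen_validation_error")
  }
  covariates <- covariates %||%
    setdiff(names(data), c(grouping, "patient_id", "completed"))
  g <- as.logical(data[[grouping]])
  rows <- list()
  for (side in c(TRUE, FALSE)) {
    sub <- data[!is.na(g) & g == side, , drop = FALSE]
    gname <- paste0(grouping, "=", side)
    if (nrow(sub) == 0) {
      warn(sprintf("Group %s is empty; summaries undefined.", gname))
    }
    for (v in covariates) {
      x <- sub[[v]]
      if (is.numeric(x)) {
        rows[[length(rows) + 1L]] <- tibble(
          group = gname, variable = v, level = NA_character_,
          n = nrow(sub), stat = "mean",
          value = if (nrow(sub) == 0) NA_real_ else mean(x, na.rm = TRUE))
      } else if (is.logical(x)) {
        rows[[length(rows) + 1L]] <- tibble(
          group = gname, variable = v, level = "TRUE",
          n = nrow(sub), stat = "pct",
          value = if (nrow(sub) == 0) NA_real_ else
            round_half_up(100 * mean(x, na.rm = TRUE), 1))
      } else {
        lev <- sort(unique(as.character(data[[v]])))
        for (l in lev) {
          rows[[length(rows) + 1L]] <- tibble(
            group = gname, variable = v, level = l,
            n = nrow(sub), stat = "pct",
            value = if (nrow(sub) == 0) NA_real_ else
              round_half_up(100 * mean(as.character(x) == l, na.rm = TRUE), 1))
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a concordance table to CSV
#'
#' Mirrors the published layout: rows are self-report categories,
#' columns the two arms, cells `"count (pct%)"`.
#'
#' @param table a `cannaphen_concordance`.
#' @param path output file.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(table, path, seed = NULL) {
  df <- tibble(
    category = c("Self-reported use in the past month",
                 "Self-reported use in past year",
                 "Self-reported non-use (never)",
                 "Ever use"),
    term_positive = vapply(concordance_categories, function(cc) {
      sprintf("%d (%s%%)", table$counts[cc, "term_positive"],
              fmt_pct(100 * table$counts[cc, "term_positive"] /
                        table$arm_totals["term_positive"]))
    }, ""),
    term_negative = vapply(concordance_categories, function(cc) {
      sprintf("%d (%s%%)", table$counts[cc, "term_negative"],
              fmt_pct(100 * table$counts[cc, "term_negative"] /
                        table$arm_totals["term_negative"]))
    }, "")
  )
  names(df)[2:3] <- sprintf(
    c("term_in_notes_past_year_n%d", "no_term_in_notes_past_year_n%d"),
    table$arm_totals)
  write_csv_with_header(df, path, seed = seed)
}
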