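test_that("recruitment rate is completed/contacted as an integer percent", {
  d <- disposition(97, 69, 1, 20, 7)
  expect_equal(recruitment_rate(d), 71L)
  expect_equal(recruitment_rate(disposition(10, 10, 0, 0, 0)), 100L)
  expect_equal(recruitment_rate(disposition(10, 0, 0, 5, 5)), 0L)
  expect_error(disposition(97, 60, 1, 20, 7),
               class = "cannaphen_validation_error")
  expect_error(recruitment_rate(disposition(0, 0, 0, 0, 0)),
               class = "cannaphen_undefined_rate_error")
})

test_that("percent rounding is half-up, not banker's", {
  expect_equal(round_half_up(42.857142, 1), 42.9)
  expect_equal(round_half_up(42.85, 1), 42.9)  # base::round gives 42.8 here
  expect_equal(round_half_up(71.134, 0), 71)
  expect_equal(round_half_up(88.888, 1), 88.9)
})

test_that("predictive values reproduce the reference concordance percentages", {
  tab <- reference_concordance()
  expect_equal(predictive_value(tab, "term_positive", "past_30d"), 42.9)
  expect_equal(predictive_value(tab, "term_positive", "past_year"), 48.6)
  expect_equal(predictive_value(tab, "term_positive", "nonuse"), 5.7)
  expect_equal(predictive_value(tab, "term_positive", "ever"), 94.3)
  expect_equal(predictive_value(tab, "term_negative", "past_30d"), 8.8)
  expect_equal(predictive_value(tab, "term_negative", "past_year"), 11.8)
  expect_equal(predictive_value(tab, "term_negative", "nonuse"), 32.4)
  expect_equal(predictive_value(tab, "term_negative", "ever"), 67.6)
})

test_that("concordance constructor enforces nesting and the ever/never split", {
  expect_error(concordance_table(
    rbind(past_30d = c(20, 3), past_year = c(17, 4),
          nonuse = c(2, 11), ever = c(33, 23)),
    c(term_positive = 35, term_negative = 34)),
    "Nesting", class = "cannaphen_validation_error")
  expect_error(concordance_table(
    rbind(past_30d = c(15, 3), past_year = c(17, 4),
          nonuse = c(5, 11), ever = c(33, 23)),
    c(term_positive = 35, term_negative = 34)),
    class = "cannaphen_validation_error")
})

test_that("build_concordance matches the nested-loop crosstab oracle", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(20:60, 1)
      ids <- sprintf("P%02d", seq_len(n))
      cls <- tibble::tibble(
        patient_id = ids,
        label = sample(c("preliminary_user", "preliminary_nonuser"), n, TRUE))
      p30 <- as.logical(rbinom(n, 1, 0.2))
      py <- p30 | as.logical(rbinom(n, 1, 0.2))
      ever <- py | as.logical(rbinom(n, 1, 0.4))
      iv <- tibble::tibble(patient_id = ids,
                           completed = as.logical(rbinom(n, 1, 0.7)),
                           used_past_30d = p30 & TRUE,
                           used_past_year = py,
                           ever_used = ever)
      iv[!iv$completed, c("used_past_30d", "used_past_year", "ever_used")] <- FALSE
      got <- build_concordance(cls, iv)
      want <- oracle_crosstab(cls, iv)
      expect_equal(got$counts, want$counts)
      expect_equal(got$arm_totals, want$totals)
    }
  })
})

test_that("build_concordance validates inputs and handles zero completions", {
  cls <- tibble::tibble(patient_id = "A", label = "preliminary_user")
  iv <- tibble::tibble(patient_id = c("A", "B"), completed = TRUE,
                       used_past_30d = FALSE, used_past_year = FALSE,
                       ever_used = TRUE)
  expect_error(build_concordance(cls, iv), "B",
               class = "cannaphen_validation_error")
  none <- build_concordance(cls, iv[0, ])
  expect_true(all(none$counts == 0))
  expect_error(predictive_value(none, "term_positive", "ever"),
               class = "cannaphen_undefined_rate_error")
})

test_that("enrichment reports the negative-arm rate first and is order-invariant", {
  tab <- reference_concordance()
  expect_equal(unname(enrichment(tab, "past_30d")), c(8.8, 42.9))
  expect_equal(unname(enrichment(tab, "ever")), c(67.6, 94.3))

  withr::with_seed(13, {
    n <- 40
    ids <- sprintf("P%02d", 1:n)
    cls <- tibble::tibble(patient_id = ids,
                          label = sample(c("preliminary_user",
                                           "preliminary_nonuser"), n, TRUE))
    ever <- as.logical(rbinom(n, 1, 0.5))
    iv <- tibble::tibble(patient_id = ids, completed = TRUE,
                         used_past_30d = FALSE, used_past_year = FALSE,
                         ever_used = ever)
    perm <- sample(n)
    a <- enrichment(build_concordance(cls, iv), "ever")
    b <- enrichment(build_concordance(cls[perm, ], iv[sample(n), ]), "ever")
    expect_equal(a, b)
  })
})

test_that("ever + never predictive values partition each arm", {
  tab <- reference_concordance()
  for (arm in c("term_positive", "term_negative")) {
    s <- predictive_value(tab, arm, "ever") + predictive_value(tab, arm, "nonuse")
    expect_lt(abs(s - 100), 0.11)  # display rounding only
    for (cc in c("past_30d", "past_year", "nonuse", "ever")) {
      pv <- predictive_value(tab, arm, cc)
      expect_gte(pv, 0); expect_lte(pv, 100)
    }
  }
})

test_that("fisher exact matches closed-form and enumeration oracles", {
  expect_equal(association_test(10, 10, 10, 10)$p_value, 1.0)
  expect_equal(association_test(5, 0, 0, 5)$p_value, 2 / 252,
               tolerance = 1e-12)
  # the ever-use table: implementation vs exhaustive tail-sum enumeration
  expect_equal(association_test(33, 2, 23, 11)$p_value,
               oracle_fisher_p(33, 2, 23, 11), tolerance = 1e-10)
  expect_error(association_test(5, 0, 5, 0),
               class = "cannaphen_validation_error")
  expect_error(association_test(-1, 2, 3, 4),
               class = "cannaphen_validation_error")
})

test_that("chi-square variants return the Pearson statistic on 1 df", {
  got <- association_test(33, 2, 23, 11, method = "chi2")
  m <- matrix(c(33, 23, 2, 11), 2)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  x2 <- sum((m - e)^2 / e)
  expect_equal(got$statistic, x2, tolerance = 1e-12)
  expect_equal(got$p_value, stats::pchisq(x2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  yates <- association_test(33, 2, 23, 11, method = "chi2_yates")
  expect_lt(yates$statistic, x2)
})

test_that("group_summary computes per-group percentages and means", {
  df <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:69),
    current_user = rep(c(TRUE, FALSE), c(18, 51)),
    tobacco_status = c(rep("current", 6), rep("former", 9), rep("never", 3),
                       rep("current", 9), rep("former", 30), rep("never", 12)),
    weekly_mets = c(rep(8, 18), rep(12, 51)))
  gs <- group_summary(df, "current_user")
  cur_tob <- gs$value[gs$group == "current_user=TRUE" &
                        gs$variable == "tobacco_status" & gs$level == "current"]
  expect_equal(cur_tob, 33.3)  # 6 of 18
  non_tob <- gs$value[gs$group == "current_user=FALSE" &
                        gs$variable == "tobacco_status" & gs$level == "current"]
  expect_equal(non_tob, round_half_up(100 * 9 / 51, 1))
  expect_equal(gs$value[gs$group == "current_user=TRUE" &
                          gs$variable == "weekly_mets"], 8)

  # random fixture vs brute-force aggregation
  withr::with_seed(3, {
    rf <- tibble::tibble(g = as.logical(rbinom(50, 1, 0.4)),
                         x = rnorm(50), f = as.logical(rbinom(50, 1, 0.3)))
  })
  gs2 <- group_summary(rf, "g")
  expect_equal(gs2$value[gs2$group == "g=TRUE" & gs2$variable == "x"],
               mean(rf$x[rf$g]))
  expect_equal(gs2$value[gs2$group == "g=FALSE" & gs2$variable == "f"],
               round_half_up(100 * sum(rf$f & !rf$g) / sum(!rf$g), 1))

  expect_warning(group_summary(rf[rf$g, ], "g"), "empty")
})

test_that("concordance CSV mirrors the published table layout", {
  tab <- reference_concordance()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_concordance(tab, tmp, seed = 1)
  got <- read.csv(tmp, comment.char = "#", check.names = FALSE)
  expect_equal(got[[2]][1], "15 (42.9%)")
  expect_equal(got[[3]][4], "23 (67.6%)")
  expect_match(names(got)[2], "35")
})
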