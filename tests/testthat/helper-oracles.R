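# Independent brute-force oracles and small fixture builders, kept
# deliberately naive so they share no code path with the implementation.

# Character-by-character whole-word scanner: checks every substring
# position with explicit boundary tests.
oracle_scan_mentions <- function(text, terms) {
  text <- stringi::stri_trans_nfc(text)
  low <- tolower(text)
  n <- nchar(low)
  is_word_char <- function(ch) grepl("^[[:alnum:]]$", ch)
  hits <- data.frame(term = character(), start = integer(), end = integer())
  for (term in terms) {
    tl <- nchar(term)
    if (tl == 0 || tl > n) next
    for (s in 1:(n - tl + 1)) {
      if (substr(low, s, s + tl - 1) != term) next
      before_ok <- s == 1 || !is_word_char(substr(low, s - 1, s - 1))
      after_ok <- (s + tl - 1) == n ||
        !is_word_char(substr(low, s + tl, s + tl))
      if (before_ok && after_ok) {
        hits <- rbind(hits, data.frame(term = term, start = s - 1L,
                                       end = s - 1L + tl))
      }
    }
  }
  hits[order(hits$start), , drop = FALSE]
}

# Random clinical-ish strings mixing dictionary words, lexicon terms,
# boundary confusers and punctuation, with random gluing so terms land
# both at word boundaries and inside larger tokens.
random_note_text <- function(n_tokens = 12) {
  vocab <- c("patient", "reports", "denies", "daily", "use", "pain",
             "TMJ", "tmj", "mjx", "MJX", "marijuana", "MARIJUANA",
             "Cannabis", "cannabis", "cannabinoid", "cannabidiol",
             "mjx2", "2mjx", "xmarijuana", "marijuanas", "mj",
             "follow-up", "hx", "smokes")
  seps <- c(" ", " ", " ", "", ".", ", ", "; ", "-", ") ", " (")
  tokens <- sample(vocab, n_tokens, replace = TRUE)
  glue <- sample(seps, n_tokens, replace = TRUE)
  paste0(paste0(tokens, glue, collapse = ""), ".")
}

# Exhaustive two-sided Fisher p: sum of all hypergeometric table
# probabilities (margins fixed) no larger than the observed table's.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c
  nn <- b + d
  k <- a + b
  xs <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(xs, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# O(n^2) nested-loop crosstab of classifications against interviews.
oracle_crosstab <- function(classifications, interviews) {
  counts <- matrix(0L, nrow = 4, ncol = 2,
                   dimnames = list(c("past_30d", "past_year", "nonuse", "ever"),
                                   c("term_positive", "term_negative")))
  totals <- c(term_positive = 0L, term_negative = 0L)
  for (i in seq_len(nrow(interviews))) {
    if (!interviews$completed[i]) next
    arm <- NA_character_
    for (j in seq_len(nrow(classifications))) {
      if (classifications$patient_id[j] == interviews$patient_id[i]) {
        arm <- if (classifications$label[j] == "preliminary_user")
          "term_positive" else "term_negative"
      }
    }
    totals[arm] <- totals[arm] + 1L
    if (interviews$used_past_30d[i]) counts["past_30d", arm] <- counts["past_30d", arm] + 1L
    if (interviews$used_past_year[i]) counts["past_year", arm] <- counts["past_year", arm] + 1L
    if (interviews$ever_used[i]) counts["ever", arm] <- counts["ever", arm] + 1L
    if (!interviews$ever_used[i]) counts["nonuse", arm] <- counts["nonuse", arm] + 1L
  }
  list(counts = counts, totals = totals)
}

# Brute-force classifier label: concatenate a patient's in-window notes
# and scan the blob.
oracle_label <- function(notes, terms, index_date, lookback_days) {
  win_start <- index_date - lookback_days + 1
  blob <- paste(notes$text[notes$note_date >= win_start &
                             notes$note_date <= index_date],
                collapse = " \n ")
  if (nrow(oracle_scan_mentions(blob, terms)) > 0)
    "preliminary_user" else "preliminary_nonuser"
}

make_note <- function(pid, text, date, note_id = paste0(pid, "-N1")) {
  tibble::tibble(patient_id = pid, note_id = note_id,
                 note_date = as.Date(date), text = text)
}

make_patient <- function(pid, age = 66L, codes = "414.01",
                         visits = as.Date("2015-06-01"),
                         deceased = FALSE, contact = TRUE) {
  tibble::tibble(patient_id = pid, age_years = as.integer(age),
                 diagnosis_codes = list(codes), visit_dates = list(visits),
                 deceased = deceased, has_contact_info = contact)
}

# The published concordance counts, used repeatedly.
reference_concordance <- function() {
  concordance_table(
    counts = rbind(past_30d = c(15L, 3L), past_year = c(17L, 4L),
                   nonuse = c(2L, 11L), ever = c(33L, 23L)),
    arm_totals = c(term_positive = 35L, term_negative = 34L))
}
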