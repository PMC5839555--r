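# Shared helpers: display rounding, seeded sub-streams, date parsing.

#' Round half-up
#'
#' Display rounding for percentages. `base::round()` rounds half to even
#' (42.85 -> 42.8); published clinical tables round half away from zero
#' (15/35 = 42.857 -> 42.9), so all user-facing percentages go through
#' this helper.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits decimal places to keep.
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(100 * 15 / 35, 1) # 42.9
#' round_half_up(100 * 69 / 97, 0) # 71
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a named sub-stream seed from a master seed so that adding one
# generator does not perturb the draws of the others. Kept below 2^31.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

# Strict ISO-8601 date parsing: NA (with no NA input) means malformed.
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  # as.Date() silently accepts impossible dates on some platforms; round-trip
  bad <- ok & (is.na(out) | format(out, "%Y-%m-%d") != x)
  out[bad] <- NA
  out
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}

stop_if_not_probability <- function(x, name) {
  if (!is_probability(x)) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name),
          class = "cannaphen_validation_error")
  }
  invisible(x)
}

# Split a semicolon-separated field into a character vector (empty -> none).
split_semis <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

fmt_pct <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}
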