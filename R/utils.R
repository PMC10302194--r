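#' Round half away from zero
#'
#' Rounding with ties going up (0.05 -> 0.1), the convention used by the
#' bundled survey table, as opposed to base R's round-half-even.
#'
#' @param x Numeric vector (non-negative values expected).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Format a prevalence percentage for display
#'
#' One decimal place, round half up; an exact 100 is printed without
#' decimals ("100"), matching common survey-table style.
#'
#' @param n_present,n Counts (numerator and denominator).
#' @return Character vector.
#' @export
format_pct <- function(n_present, n) {
  pct <- round_half_up(100 * n_present / n, 1)
  out <- sprintf("%.1f", pct)
  out[!is.na(pct) & pct == 100] <- "100"
  out[is.na(pct)] <- NA_character_
  out
}

#' Format a p-value for display
#'
#' Rounds to three decimals (half up) first; values whose rounded form falls
#' below `threshold` render as "<0.01". This ordering means p = 0.0092 prints
#' as "0.009" rather than "<0.01".
#'
#' @param p Numeric p-values (NA allowed).
#' @param threshold Rounded values strictly below this print as "<0.01".
#' @param na_label Label used for NA (not-applicable) entries.
#' @return Character vector.
#' @export
format_p <- function(p, threshold = 0.005, na_label = "n.a.") {
  r <- round_half_up(p, 3)
  out <- sprintf("%.3f", r)
  out[!is.na(r) & r < threshold] <- "<0.01"
  out[is.na(p)] <- na_label
  out
}

# percentage helper used for headline figures (returns numeric, 1 d.p.)
headline_pct <- function(n_part, n_total) {
  round_half_up(100 * n_part / n_total, 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# deterministic 32-bit polynomial hash of a string (for per-record RNG streams)
string_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(enc2utf8(s))) h <- (h * 31 + c) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}
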