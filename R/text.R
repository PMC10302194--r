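#' Normalize free label text for matching
#'
#' Lowercases, folds accents/diacritics (Latin and Greek, so
#' \code{"λεκιθίνη"} matches
#' \code{"λεκιθινη"}), unifies
#' punctuation variants (curly quotes, long dashes, the Greek ano teleia),
#' folds the Greek final sigma, and collapses whitespace. Deterministic and
#' idempotent; all lexicon matching operates on this form.
#'
#' @param x Character vector (NA passed through).
#' @return Normalized character vector.
#' @export
normalize_text <- function(x) {
  out <- stringi::stri_trans_nfc(as.character(x))
  out <- stringi::stri_trans_tolower(out)
  out <- stringi::stri_replace_all_regex(out, "[‘’ʼ´`]", "'")
  out <- stringi::stri_replace_all_regex(out, "[“”«»]", "\"")
  out <- stringi::stri_replace_all_regex(out, "[–—−]", "-")
  out <- stringi::stri_replace_all_fixed(out, "·", ";") # Greek ano teleia
  out <- stringi::stri_trans_nfd(out)
  out <- stringi::stri_replace_all_regex(out, "\\p{Mn}+", "")
  out <- stringi::stri_trans_nfc(out)
  out <- stringi::stri_replace_all_fixed(out, "ς", "σ") # final sigma
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  stringi::stri_trim_both(out)
}

# split a string on sep characters at parenthesis depth 0; best effort on
# unbalanced input (depth never goes below zero)
split_top_level <- function(s, seps = c(",", ";")) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  piece <- character(0)
  out <- character(0)
  balanced <- TRUE
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      if (depth == 0L) balanced <- FALSE else depth <- depth - 1L
    }
    if (depth == 0L && ch %in% seps) {
      out <- c(out, paste(piece, collapse = ""))
      piece <- character(0)
    } else {
      piece <- c(piece, ch)
    }
  }
  out <- c(out, paste(piece, collapse = ""))
  if (depth != 0L) balanced <- FALSE
  attr(out, "balanced") <- balanced
  out
}

# extract top-level parenthetical groups of a phrase
extract_parentheticals <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  groups <- character(0)
  buf <- character(0)
  for (ch in chars) {
    if (ch == "(") {
      depth <- depth + 1L
      if (depth == 1L) next
    }
    if (ch == ")") {
      if (depth > 0L) depth <- depth - 1L
      if (depth == 0L) {
        groups <- c(groups, paste(buf, collapse = ""))
        buf <- character(0)
        next
      }
    }
    if (depth >= 1L) buf <- c(buf, ch)
  }
  if (depth > 0L && length(buf)) groups <- c(groups, paste(buf, collapse = ""))
  groups
}

# strip percentage tokens; returns cleaned string with attr "percentage"
strip_percentage <- function(s) {
  pct_re <- "\\d+(?:[.,]\\d+)?\\s*%"
  m <- stringi::stri_extract_first_regex(s, pct_re)
  pct <- NA_real_
  if (!is.na(m)) {
    pct <- as.numeric(stringi::stri_replace_all_fixed(
      stringi::stri_replace_all_regex(m, "[%\\s]", ""), ",", "."))
  }
  out <- stringi::stri_replace_all_regex(s, pct_re, " ")
  out <- stringi::stri_replace_all_regex(out, "\\(\\s*\\)", " ")
  out <- stringi::stri_trim_both(stringi::stri_replace_all_regex(out, "\\s+", " "))
  out <- stringi::stri_replace_all_regex(out, "^[.,;:]+|[.,;:]+$", "")
  out <- stringi::stri_trim_both(out)
  attr(out, "percentage") <- pct
  out
}

#' Split a normalized ingredient list into phrases
#'
#' Splits on commas/semicolons outside parentheses. Each top-level phrase is
#' kept whole (including any additive-function prefix such as
#' "emulsifier:"), and its parenthetical sub-ingredients and after-colon
#' remainders are additionally exposed as child phrases. Percentages such as
#' "(13%)" are stripped from the matchable phrase but recorded in the
#' `percentage` column.
#'
#' @param text A single normalized ingredient list (see [normalize_text()]).
#' @return A tibble with columns `raw` (the phrase as written), `phrase`
#'   (cleaned, percentage-stripped form used for matching), `parent`
#'   (integer row index of the enclosing phrase, NA for top-level), and
#'   `percentage`. Unbalanced parentheses yield a warning and a best-effort
#'   split.
#' @export
split_ingredient_list <- function(text) {
  empty <- tibble::tibble(raw = character(), phrase = character(),
                          parent = integer(), percentage = double())
  if (length(text) != 1L) stop("split_ingredient_list() expects a single string")
  if (is.na(text) || !nzchar(stringi::stri_trim_both(text))) return(empty)

  rows <- list()
  add_row <- function(raw, parent) {
    cleaned <- strip_percentage(raw)
    phrase <- as.character(cleaned)
    if (!nzchar(phrase)) return(NA_integer_)
    rows[[length(rows) + 1L]] <<- list(
      raw = stringi::stri_trim_both(raw), phrase = phrase,
      parent = parent, percentage = attr(cleaned, "percentage"))
    length(rows)
  }
  descend <- function(raw, parent, depth) {
    idx <- add_row(raw, parent)
    if (is.na(idx) || depth > 4L) return(invisible(NULL))
    # additive-function prefix: "emulsifier: lecithins (soy)" exposes
    # "lecithins (soy)" as a child, whose own parenthetical then yields "soy"
    m <- stringi::stri_match_first_regex(raw, "^[^(),:;]{1,40}:\\s*(.+)$")
    kids <- if (!is.na(m[1, 2])) m[1, 2] else extract_parentheticals(raw)
    for (k in kids) {
      pieces <- split_top_level(k)
      for (p in pieces) {
        p <- stringi::stri_trim_both(p)
        if (nzchar(p)) descend(p, idx, depth + 1L)
      }
    }
    invisible(NULL)
  }

  top <- split_top_level(text)
  if (!attr(top, "balanced")) {
    warning("unbalanced parentheses in ingredient list; best-effort split",
            call. = FALSE)
  }
  for (t in top) {
    t <- stringi::stri_trim_both(t)
    if (nzchar(t)) descend(t, NA_integer_, 1L)
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}
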