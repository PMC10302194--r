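#' The 14 EU-regulated allergen identifiers
#'
#' Stable identifiers for the 14 substances whose presence as an ingredient
#' must be declared on EU food labels (Annex II): cereals containing gluten,
#' crustaceans, eggs, fish, peanuts, soybeans, milk, tree nuts, celery,
#' mustard, sesame, sulphites, lupin, and mollusks.
#'
#' @return Character vector of length 14, in fixed order.
#' @export
eu_allergens <- function() {
  c("gluten_cereals", "crustaceans", "eggs", "fish", "peanuts", "soybeans",
    "milk", "tree_nuts", "celery", "mustard", "sesame", "sulphites",
    "lupin", "mollusks")
}

e_number_terms <- function(ranges) {
  if (is.null(ranges) || !length(ranges)) return(character(0))
  nums <- unlist(lapply(ranges, function(r) seq(r[[1]], r[[2]])))
  c(sprintf("e%d", nums), sprintf("e %d", nums), sprintf("e-%d", nums))
}

term_regex <- function(terms) {
  terms <- unique(terms[nzchar(terms)])
  if (!length(terms)) return(NA_character_)
  paste0("\\b(?:", paste(stringr::str_escape(terms), collapse = "|"), ")\\b")
}

#' Load and compile an allergen lexicon
#'
#' The lexicon file is JSON with an `allergens` object keyed by the 14
#' identifiers of [eu_allergens()], each with `canonical_terms`,
#' `derivative_terms` (e.g. whey -> milk, spelt -> gluten_cereals),
#' `exclusion_patterns` (regular expressions for negation/claim phrases such
#' as "gluten-free" that must not count as presence), and optional
#' `e_number_ranges` (e.g. E220-E228 -> sulphites); plus top-level
#' `trigger_phrases` (precautionary-statement openers) and
#' `contains_statement_phrases` (post-list "contains" openers, counted as
#' ingredient declarations). All terms are normalized on load, so Greek or
#' accented vocabularies work unchanged.
#'
#' @param path Lexicon JSON file; the bundled English default when NULL.
#' @return An `allergen_lexicon` object with compiled match regexes.
#' @export
load_allergen_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "allergen_lexicon_en.json",
                                package = "allergenova", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- eu_allergens()
  if (!setequal(names(raw$allergens), ids)) {
    stop("allergen lexicon must define exactly the 14 allergen identifiers; ",
         "missing: ", paste(setdiff(ids, names(raw$allergens)), collapse = ", "),
         "; unknown: ", paste(setdiff(names(raw$allergens), ids), collapse = ", "),
         call. = FALSE)
  }
  allergens <- lapply(ids, function(id) {
    entry <- raw$allergens[[id]]
    canonical <- normalize_text(unlist(entry$canonical_terms))
    if (!length(canonical) || all(!nzchar(canonical))) {
      stop("allergen lexicon: '", id, "' has no canonical terms", call. = FALSE)
    }
    derivative <- normalize_text(unlist(entry$derivative_terms) %||% character(0))
    ranges <- entry$e_number_ranges
    if (is.matrix(ranges)) ranges <- asplit(ranges, 1)
    terms <- c(canonical, derivative, e_number_terms(ranges))
    list(
      canonical_terms = canonical,
      derivative_terms = derivative,
      exclusion_patterns = normalize_text(unlist(entry$exclusion_patterns) %||% character(0)),
      regex = term_regex(terms)
    )
  })
  names(allergens) <- ids
  structure(list(
    name = raw$name %||% basename(path),
    version = raw$version %||% "unversioned",
    allergens = allergens,
    trigger_phrases = normalize_text(unlist(raw$trigger_phrases)),
    contains_statement_phrases = normalize_text(unlist(raw$contains_statement_phrases)),
    path = path
  ), class = "allergen_lexicon")
}

#' @export
print.allergen_lexicon <- function(x, ...) {
  cat(sprintf("Allergen lexicon '%s' (%s): 14 allergens, %d trigger phrases\n",
              x$name, x$version, length(x$trigger_phrases)))
  invisible(x)
}
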