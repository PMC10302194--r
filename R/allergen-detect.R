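as_match_texts <- function(phrases) {
  if (is.data.frame(phrases)) phrases$phrase else normalize_text(phrases)
}

# remove the spans matched by an allergen's exclusion (claim) patterns from
# each text; returns texts with attr "claims" (text index, pattern) logged
apply_exclusion_patterns <- function(texts, patterns) {
  claims <- tibble::tibble(text = character(), pattern = character())
  if (length(patterns)) {
    for (pat in patterns) {
      hit <- stringr::str_detect(texts, pat)
      if (any(hit)) {
        claims <- dplyr::bind_rows(claims,
          tibble::tibble(text = texts[hit], pattern = pat))
        texts[hit] <- stringr::str_replace_all(texts[hit], pat, " ")
      }
    }
  }
  attr(texts, "claims") <- claims
  texts
}

#' Detect allergens declared as ingredients
#'
#' An allergen is reported when any ingredient phrase, sub-ingredient, or
#' post-list "contains" statement matches one of its canonical or derivative
#' terms as a whole word/phrase on normalized text. Claim constructions
#' ("gluten-free") suppress the claimed term within that phrase only - other
#' matches in the same phrase still count - and are logged on the result as
#' the `claims` attribute.
#'
#' @param phrases Output of [split_ingredient_list()], or a character vector
#'   of phrases.
#' @param contains_statements Optional character vector of post-ingredient
#'   "contains ..." statements (counted as ingredient declarations).
#' @param lexicon An [allergen_lexicon][load_allergen_lexicon].
#' @return Character vector of allergen identifiers (in canonical order),
#'   with a `claims` attribute logging suppressed claim matches.
#' @export
detect_ingredient_allergens <- function(phrases, contains_statements = character(),
                                        lexicon = load_allergen_lexicon()) {
  texts <- c(as_match_texts(phrases), normalize_text(contains_statements))
  texts <- texts[!is.na(texts) & nzchar(texts)]
  claims <- tibble::tibble(text = character(), pattern = character(),
                           allergen = character())
  found <- character(0)
  for (id in eu_allergens()) {
    entry <- lexicon$allergens[[id]]
    txt <- apply_exclusion_patterns(texts, entry$exclusion_patterns)
    cl <- attr(txt, "claims")
    if (nrow(cl)) claims <- dplyr::bind_rows(claims, dplyr::mutate(cl, allergen = id))
    if (length(txt) && any(stringr::str_detect(txt, entry$regex))) {
      found <- c(found, id)
    }
  }
  structure(found, claims = claims)
}

#' Detect allergens declared in precautionary statements
#'
#' A statement qualifies as precautionary when it contains one of the
#' lexicon's trigger phrases ("may contain traces of", "manufactured in a
#' facility that also processes", "may be present", ...). All trigger
#' variants map to the single trace status: adventitious presence and
#' presence of traces are not distinguished. A qualifying statement naming
#' no recognizable allergen term yields a warning.
#'
#' @param precaution_texts Character vector of label statements.
#' @inheritParams detect_ingredient_allergens
#' @return Character vector of allergen identifiers (canonical order).
#' @export
detect_precautionary_allergens <- function(precaution_texts,
                                           lexicon = load_allergen_lexicon()) {
  texts <- normalize_text(precaution_texts)
  texts <- texts[!is.na(texts) & nzchar(texts)]
  if (!length(texts)) return(character(0))
  triggered <- vapply(texts, function(t) {
    any(stringi::stri_detect_fixed(t, lexicon$trigger_phrases))
  }, logical(1), USE.NAMES = FALSE)
  texts <- texts[triggered]
  if (!length(texts)) return(character(0))
  found <- character(0)
  for (id in eu_allergens()) {
    entry <- lexicon$allergens[[id]]
    txt <- apply_exclusion_patterns(texts, entry$exclusion_patterns)
    if (any(stringr::str_detect(txt, entry$regex))) found <- c(found, id)
  }
  matched_any <- Reduce(`|`, lapply(eu_allergens(), function(id) {
    stringr::str_detect(texts, lexicon$allergens[[id]]$regex)
  }))
  if (any(!matched_any)) {
    warning("precautionary statement(s) with trigger phrase but no ",
            "recognizable allergen term: ",
            paste(utils::head(texts[!matched_any], 3), collapse = "; "),
            call. = FALSE)
  }
  found
}

# split precaution texts into contains-statements (ingredient declarations)
# and trigger statements (trace declarations); trigger takes precedence
partition_precaution_texts <- function(precaution_texts, lexicon) {
  texts <- normalize_text(precaution_texts)
  texts <- texts[!is.na(texts) & nzchar(texts)]
  if (!length(texts)) return(list(contains = character(0), trace = character(0)))
  is_trigger <- vapply(texts, function(t) {
    any(stringi::stri_detect_fixed(t, lexicon$trigger_phrases))
  }, logical(1), USE.NAMES = FALSE)
  is_contains <- !is_trigger & vapply(texts, function(t) {
    any(stringi::stri_startswith_fixed(t, lexicon$contains_statement_phrases))
  }, logical(1), USE.NAMES = FALSE)
  list(contains = texts[is_contains], trace = texts[is_trigger])
}

allergen_status_levels <- c("absent", "trace", "ingredient")

#' Build the per-record allergen profile
#'
#' Combines ingredient-declared and precaution-declared detection into one
#' status per allergen, with the precedence ingredient > trace > absent
#' (statuses are ordered by potential exposure risk; an allergen declared
#' both ways is counted once, as an ingredient).
#'
#' @param record A single record (one-row tibble or list with
#'   `ingredient_text` and `precaution_texts`).
#' @inheritParams detect_ingredient_allergens
#' @return A list with `statuses` (named character vector over all 14
#'   allergens), and counts `n_ingredient`, `n_trace`, `n_any`,
#'   `contains_any`.
#' @export
build_profile <- function(record, lexicon = load_allergen_lexicon()) {
  ingredient_text <- if (is.data.frame(record)) record$ingredient_text[[1]] else record$ingredient_text
  precaution_texts <- if (is.data.frame(record)) record$precaution_texts[[1]] else record$precaution_texts
  phrases <- split_ingredient_list(normalize_text(ingredient_text %||% NA_character_))
  parts <- partition_precaution_texts(precaution_texts %||% character(0), lexicon)
  ing <- detect_ingredient_allergens(phrases, parts$contains, lexicon)
  tr <- detect_precautionary_allergens(parts$trace, lexicon)
  statuses <- stats::setNames(rep("absent", 14L), eu_allergens())
  statuses[intersect(names(statuses), tr)] <- "trace"
  statuses[intersect(names(statuses), ing)] <- "ingredient"
  list(
    statuses = statuses,
    n_ingredient = sum(statuses == "ingredient"),
    n_trace = sum(statuses == "trace"),
    n_any = sum(statuses != "absent"),
    contains_any = any(statuses != "absent"),
    claims = attr(ing, "claims")
  )
}

#' Build allergen profiles for a whole record set
#'
#' @param records A validated records tibble (retained records).
#' @inheritParams detect_ingredient_allergens
#' @return A long tibble with one row per record x allergen: `product_id`,
#'   `allergen`, `status` (factor absent < trace < ingredient).
#' @export
build_profiles <- function(records, lexicon = load_allergen_lexicon()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- build_profile(list(
      ingredient_text = records$ingredient_text[[i]],
      precaution_texts = records$precaution_texts[[i]]), lexicon)
    tibble::tibble(product_id = records$product_id[[i]],
                   allergen = names(p$statuses),
                   status = p$statuses)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(product_id = character(), allergen = character(),
                          status = character())
  }
  out$allergen <- factor(out$allergen, levels = eu_allergens())
  out$status <- factor(out$status, levels = allergen_status_levels, ordered = TRUE)
  out
}

#' Summarize profiles into per-record allergen counts
#'
#' @param profiles Long profile tibble from [build_profiles()].
#' @return A tibble with one row per product: `n_ingredient`, `n_trace`,
#'   `n_any` (= n_ingredient + n_trace), and `contains_any`.
#' @export
profile_counts <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$product_id) |>
    dplyr::summarise(
      n_ingredient = sum(.data$status == "ingredient"),
      n_trace = sum(.data$status == "trace"),
      n_any = sum(.data$status != "absent"),
      contains_any = sum(.data$status != "absent") >= 1L,
      .groups = "drop")
}
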