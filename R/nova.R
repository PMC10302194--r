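#' Load and compile a NOVA marker lexicon
#'
#' JSON file with `marker_classes` (each class - sweeteners, flavourings,
#' flavour enhancers, emulsifiers, bulking agents, thickeners, antioxidants,
#' protein isolates/concentrates, added vitamins/minerals,
#' hydrolyzed/extruded ingredients, food extracts - carrying `terms` and
#' optional `e_number_ranges`), `culinary_terms` (salt, sugar, oils, starch,
#' butter/animal fat, honey), `water_terms`, and a `subcategory_overrides`
#' table of subcategories that are industrially formulated by construction
#' (used only when override checking is enabled).
#'
#' @param path Marker lexicon JSON; the bundled English default when NULL.
#' @return A `marker_lexicon` object with compiled regexes.
#' @export
load_marker_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "nova_markers_en.json",
                                package = "allergenova", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$marker_classes) || !length(raw$marker_classes)) {
    stop("marker lexicon must define marker_classes", call. = FALSE)
  }
  culinary <- normalize_text(unlist(raw$culinary_terms))
  classes <- lapply(raw$marker_classes, function(entry) {
    terms <- normalize_text(unlist(entry$terms) %||% character(0))
    ranges <- entry$e_number_ranges
    if (is.matrix(ranges)) ranges <- asplit(ranges, 1)
    overlap <- intersect(terms, culinary)
    if (length(overlap)) {
      stop("marker lexicon: term(s) shared between a marker class and ",
           "culinary_terms: ", paste(overlap, collapse = ", "), call. = FALSE)
    }
    list(terms = terms, regex = term_regex(c(terms, e_number_terms(ranges))))
  })
  structure(list(
    name = raw$name %||% basename(path),
    version = raw$version %||% "unversioned",
    marker_classes = classes,
    culinary_terms = culinary,
    culinary_regex = term_regex(culinary),
    water_regex = term_regex(normalize_text(unlist(raw$water_terms) %||% "water")),
    subcategory_overrides = unlist(raw$subcategory_overrides) %||% character(0),
    path = path
  ), class = "marker_lexicon")
}

#' Assign a NOVA processing grade from an ingredient list
#'
#' Decision cascade on the parsed ingredient phrases:
#' 1. any ultra-processing marker match (marker-class term or E-number), or
#'    an industrial-formulation override for the record's subcategory when
#'    `overrides_enabled`, assigns grade 4;
#' 2. otherwise a single-ingredient product (water not counted) whose sole
#'    ingredient is a culinary term (salt, sugar, oil, starch, butter,
#'    honey) is grade 2;
#' 3. otherwise a multi-ingredient list containing at least one culinary
#'    term is grade 3 (a recipe combining foods with a culinary ingredient);
#' 4. otherwise grade 1 (unprocessed/minimally processed), including
#'    single-ingredient products whose ingredient is not culinary.
#'
#' With `strict_nova4_markers = TRUE` the literal reading is applied
#' instead: plain culinary terms added to a multi-ingredient recipe also
#' count as grade-4 markers, which leaves grade 3 essentially unpopulated
#' and is therefore off by default.
#'
#' Ingredient count is recorded in the trace but never decides a grade by
#' itself.
#'
#' @param record A single record (one-row tibble or list with
#'   `ingredient_text`, `subcategory`).
#' @param markers A [marker_lexicon][load_marker_lexicon].
#' @param strict_nova4_markers Literal marker reading (see above).
#' @param overrides_enabled Apply the lexicon's subcategory override table.
#' @return A `nova_trace` list: `grade` (integer 1-4), `rule_fired`,
#'   `matched_markers` (tibble phrase x marker class), `n_ingredients`
#'   (top-level phrase count).
#' @export
classify_nova <- function(record, markers = load_marker_lexicon(),
                          strict_nova4_markers = FALSE,
                          overrides_enabled = FALSE) {
  ingredient_text <- if (is.data.frame(record)) record$ingredient_text[[1]] else record$ingredient_text
  subcategory <- if (is.data.frame(record)) record$subcategory[[1]] else record$subcategory
  phrases <- split_ingredient_list(normalize_text(ingredient_text %||% NA_character_))
  if (!nrow(phrases)) {
    stop("classification error: empty ingredient list (record should have ",
         "been excluded)", call. = FALSE)
  }
  n_top <- sum(is.na(phrases$parent))

  matched <- dplyr::bind_rows(lapply(names(markers$marker_classes), function(cl) {
    hit <- stringr::str_detect(phrases$phrase, markers$marker_classes[[cl]]$regex)
    tibble::tibble(phrase = phrases$phrase[hit], class = cl)
  }))
  if (!nrow(matched)) {
    matched <- tibble::tibble(phrase = character(), class = character())
  }

  trace <- function(grade, rule, mm = matched) {
    structure(list(grade = as.integer(grade), rule_fired = rule,
                   matched_markers = mm, n_ingredients = n_top),
              class = "nova_trace")
  }

  if (overrides_enabled && !is.null(subcategory) && !is.na(subcategory) &&
      subcategory %in% names(markers$subcategory_overrides)) {
    return(trace(markers$subcategory_overrides[[subcategory]], "industrial_override"))
  }
  if (nrow(matched)) return(trace(4L, "nova4_marker"))

  top <- phrases[is.na(phrases$parent), ]
  non_water <- top$phrase[!stringr::str_detect(top$phrase, markers$water_regex)]
  culinary_hit <- stringr::str_detect(non_water, markers$culinary_regex)

  if (length(non_water) == 1L && any(culinary_hit)) {
    return(trace(2L, "single_culinary"))
  }
  if (length(non_water) > 1L && any(culinary_hit)) {
    if (strict_nova4_markers) {
      mm <- tibble::tibble(phrase = non_water[culinary_hit],
                           class = "culinary_as_marker")
      return(trace(4L, "culinary_marker_strict", mm))
    }
    return(trace(3L, "culinary_in_recipe"))
  }
  trace(1L, "minimal")
}

#' @export
print.nova_trace <- function(x, ...) {
  cat(sprintf("NOVA%d (rule: %s; %d top-level ingredient(s)",
              x$grade, x$rule_fired, x$n_ingredients))
  if (nrow(x$matched_markers)) {
    cat(sprintf("; markers: %s",
                paste(unique(x$matched_markers$class), collapse = ", ")))
  }
  cat(")\n")
  invisible(x)
}

#' Classify every record of a set
#'
#' @param records Validated records tibble (retained records).
#' @inheritParams classify_nova
#' @return A tibble with one row per record: `product_id`, `nova` (integer),
#'   `rule_fired`, `n_ingredients`, and `matched_markers` (list-column of
#'   tibbles). Per-record classification errors are re-raised with the
#'   offending product id.
#' @export
classify_all <- function(records, markers = load_marker_lexicon(),
                         strict_nova4_markers = FALSE,
                         overrides_enabled = FALSE) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    tr <- tryCatch(
      classify_nova(list(ingredient_text = records$ingredient_text[[i]],
                         subcategory = records$subcategory[[i]]),
                    markers, strict_nova4_markers, overrides_enabled),
      error = function(e) {
        stop("record '", records$product_id[[i]], "': ", conditionMessage(e),
             call. = FALSE)
      })
    tibble::tibble(product_id = records$product_id[[i]], nova = tr$grade,
                   rule_fired = tr$rule_fired, n_ingredients = tr$n_ingredients,
                   matched_markers = list(tr$matched_markers))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(product_id = character(), nova = integer(),
                          rule_fired = character(), n_ingredients = integer(),
                          matched_markers = list())
  }
  out
}
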