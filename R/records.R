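record_columns <- c("product_id", "name", "category", "subcategory",
                    "ingredient_text", "precaution_texts",
                    "ingredient_list_readable", "all_package_sides_available")

#' Validate a set of branded-food records
#'
#' Checks the record schema: required columns, unique product ids,
#' subcategories known to the taxonomy with parents matching the `category`
#' column, and internal consistency (a record flagged as having a readable
#' ingredient list must actually carry ingredient text).
#'
#' @param records A tibble of records (see [read_records()] for the schema).
#' @param taxonomy A `food_taxonomy`, by default the bundled survey scheme.
#' @param permissive If TRUE, records with unknown subcategories are moved to
#'   a quarantine attribute instead of raising an error.
#' @return The validated records tibble (invisibly quarantining offenders
#'   under `attr(, "quarantined")` when `permissive`).
#' @export
validate_records <- function(records, taxonomy = default_taxonomy(),
                             permissive = FALSE) {
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols)) {
    stop("record schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- tibble::as_tibble(records)[record_columns]
  if (!is.list(records$precaution_texts)) {
    records$precaution_texts <- as.list(records$precaution_texts)
  }
  records$precaution_texts <- lapply(records$precaution_texts, function(x) {
    x <- as.character(x)
    x[!is.na(x) & nzchar(x)]
  })
  dup <- records$product_id[duplicated(records$product_id)]
  if (length(dup)) {
    stop("duplicate product_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  unknown <- !(records$subcategory %in% taxonomy$subcategory)
  quarantined <- records[0, ]
  if (any(unknown)) {
    if (!permissive) {
      stop("taxonomy error: unknown subcategory for ",
           paste(unique(records$subcategory[unknown]), collapse = ", "),
           call. = FALSE)
    }
    quarantined <- records[unknown, ]
    records <- records[!unknown, ]
  }
  parent <- taxonomy$category[match(records$subcategory, taxonomy$subcategory)]
  bad_parent <- !is.na(parent) & parent != records$category
  if (any(bad_parent)) {
    stop("taxonomy error: category does not match subcategory parent for ",
         paste(records$product_id[bad_parent], collapse = ", "), call. = FALSE)
  }
  contradictory <- records$ingredient_list_readable &
    (is.na(records$ingredient_text) | !nzchar(records$ingredient_text))
  if (any(contradictory)) {
    stop("validation error: ingredient_list_readable is TRUE but ",
         "ingredient_text is missing for ",
         paste(records$product_id[contradictory], collapse = ", "),
         call. = FALSE)
  }
  attr(records, "quarantined") <- quarantined
  records
}

#' Read branded-food records from CSV or JSON
#'
#' CSV columns (exact names): `product_id`, `name`, `category`,
#' `subcategory`, `ingredient_text`, `precaution_texts` (multiple statements
#' joined with `precaution_sep`), `ingredient_list_readable`,
#' `all_package_sides_available`. JSON: an array of objects with the same
#' keys, `precaution_texts` being an array of strings.
#'
#' @param path Input file.
#' @param format `"csv"` or `"json"`.
#' @param taxonomy Taxonomy used for validation.
#' @param precaution_sep Separator joining multiple precautionary statements
#'   in the CSV dialect.
#' @param permissive Quarantine unknown subcategories instead of erroring.
#' @return A validated tibble of records, with a `provenance` attribute.
#' @export
read_records <- function(path, format = c("csv", "json"),
                         taxonomy = default_taxonomy(), precaution_sep = "|",
                         permissive = FALSE) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          na = character(), progress = FALSE)
    missing_cols <- setdiff(record_columns, names(df))
    if (length(missing_cols)) {
      stop("record schema error: missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df$ingredient_text <- dplyr::if_else(nzchar(df$ingredient_text),
                                         df$ingredient_text, NA_character_)
    df$precaution_texts <- ifelse(nzchar(df$precaution_texts),
                                  df$precaution_texts, NA_character_)
    df$precaution_texts <- lapply(
      stringi::stri_split_fixed(df$precaution_texts, precaution_sep),
      function(x) x[!is.na(x) & nzchar(x)])
    df$ingredient_list_readable <- as.logical(df$ingredient_list_readable)
    df$all_package_sides_available <- as.logical(df$all_package_sides_available)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- dplyr::bind_rows(lapply(raw, function(r) {
      tibble::tibble(
        product_id = r$product_id %||% NA_character_,
        name = r$name %||% NA_character_,
        category = r$category %||% NA_character_,
        subcategory = r$subcategory %||% NA_character_,
        ingredient_text = r$ingredient_text %||% NA_character_,
        precaution_texts = list(unlist(r$precaution_texts) %||% character(0)),
        ingredient_list_readable = isTRUE(r$ingredient_list_readable),
        all_package_sides_available = isTRUE(r$all_package_sides_available)
      )
    }))
    if (!nrow(df)) {
      df <- tibble::tibble(product_id = character(), name = character(),
                           category = character(), subcategory = character(),
                           ingredient_text = character(),
                           precaution_texts = list(),
                           ingredient_list_readable = logical(),
                           all_package_sides_available = logical())
    }
  }
  out <- validate_records(df, taxonomy = taxonomy, permissive = permissive)
  attr(out, "provenance") <- paste0(format, ":", path)
  out
}

#' Write branded-food records to CSV or JSON
#'
#' Inverse of [read_records()]: a written file read back yields the same
#' record set (text fields preserved, UTF-8 throughout), and writing the
#' same set twice yields byte-identical files.
#'
#' @inheritParams read_records
#' @param records A validated records tibble.
#' @export
write_records <- function(records, path, format = c("csv", "json"),
                          precaution_sep = "|") {
  format <- match.arg(format)
  records <- tibble::as_tibble(records)[record_columns]
  if (format == "csv") {
    flat <- records
    flat$precaution_texts <- vapply(records$precaution_texts,
                                    paste, character(1), collapse = precaution_sep)
    flat$ingredient_text <- dplyr::coalesce(flat$ingredient_text, "")
    readr::write_csv(flat, path, na = "", progress = FALSE)
  } else {
    objs <- lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      list(product_id = r$product_id, name = r$name, category = r$category,
           subcategory = r$subcategory,
           ingredient_text = r$ingredient_text,
           precaution_texts = r$precaution_texts[[1]],
           ingredient_list_readable = r$ingredient_list_readable,
           all_package_sides_available = r$all_package_sides_available)
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = TRUE,
                         na = "null", always_decimal = FALSE)
  }
  invisible(path)
}

#' Apply the completeness exclusion filter
#'
#' Retains records whose ingredient list is readable and whose package was
#' imaged on all sides (precautionary statements may sit on any side, so an
#' incompletely imaged package cannot be assessed for traces). A record
#' failing both checks is counted once, under the unreadable-list reason.
#'
#' @param records A validated records tibble.
#' @return A list with `retained` (records tibble) and `log`, an
#'   `exclusion_log` with counts and per-record reasons.
#' @export
apply_exclusions <- function(records) {
  unreadable <- !records$ingredient_list_readable
  incomplete <- !unreadable & !records$all_package_sides_available
  retained <- records[!unreadable & !incomplete, ]
  log <- structure(list(
    n_input = nrow(records),
    n_unreadable_excluded = sum(unreadable),
    n_incomplete_package_excluded = sum(incomplete),
    n_retained = nrow(retained),
    excluded = tibble::tibble(
      product_id = records$product_id[unreadable | incomplete],
      reason = c("unreadable_ingredient_list", "incomplete_package_imaging")[
        2L - unreadable[unreadable | incomplete]]
    )
  ), class = "exclusion_log")
  list(retained = retained, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf(
    "Exclusion log: %d input, %d unreadable list, %d incomplete imaging -> %d retained\n",
    x$n_input, x$n_unreadable_excluded, x$n_incomplete_package_excluded,
    x$n_retained))
  invisible(x)
}
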