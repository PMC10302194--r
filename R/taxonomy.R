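#' Load a food taxonomy from JSON
#'
#' A taxonomy is a two-level scheme: categories, each with an ordered list of
#' subcategories. The file format is a JSON object mapping category name to
#' an array of subcategory names.
#'
#' @param path Path to a taxonomy JSON file.
#' @return A tibble with columns `category` and `subcategory` (one row per
#'   subcategory, in file order), of class `food_taxonomy`.
#' @export
load_taxonomy <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("taxonomy file must be a JSON object mapping category -> subcategories",
         call. = FALSE)
  }
  tax <- tibble::tibble(
    category = rep(names(raw), lengths(raw)),
    subcategory = unlist(raw, use.names = FALSE)
  )
  validate_taxonomy(tax)
}

#' @rdname load_taxonomy
#' @param tax A candidate taxonomy tibble.
#' @export
validate_taxonomy <- function(tax) {
  stopifnot(is.data.frame(tax), all(c("category", "subcategory") %in% names(tax)))
  if (anyDuplicated(tax$subcategory)) {
    stop("duplicate subcategory names: ",
         paste(unique(tax$subcategory[duplicated(tax$subcategory)]), collapse = ", "),
         call. = FALSE)
  }
  tax <- tibble::as_tibble(tax[c("category", "subcategory")])
  class(tax) <- c("food_taxonomy", class(tax))
  tax
}

#' The default Greek branded-food survey taxonomy
#'
#' The 13-category / 41-subcategory scheme used by the bundled market-survey
#' reference data, shipped as a versioned JSON file under `extdata` so that
#' other market taxonomies can be swapped in.
#'
#' @return A `food_taxonomy` tibble (41 rows).
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "taxonomy_greek_market.json",
                            package = "allergenova", mustWork = TRUE))
}
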