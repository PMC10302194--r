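#' Reference prevalence counts from the Greek branded-food market survey
#'
#' The published per-subcategory prevalence summary that the statistical
#' layer is validated against: for each of the 41 subcategories (13
#' categories), the NOVA groups present, the group size `n`, the number of
#' products declaring at least one allergen (ingredient or precautionary
#' scope) `n_present`, and the p-value label as printed (`p_printed`,
#' repeated across the subcategory's rows; "n.a." where the comparison was
#' not applicable). Counts are reproduced verbatim, including the source's
#' own internal inconsistencies (its rows sum to 4590 although the stated
#' analyzable set is 4587, and the "Starchy root or potato" cell is
#' internally inconsistent); see the package vignette.
#'
#' @return A tibble with columns `category`, `subcategory`, `nova`, `n`,
#'   `n_present`, `p_printed`.
#' @export
reference_survey_counts <- function() {
  tbl <- function(category, subcategory, p, ...) {
    rows <- list(...)
    tibble::tibble(
      category = category, subcategory = subcategory,
      nova = vapply(rows, `[[`, integer(1), 1L),
      n = vapply(rows, `[[`, integer(1), 2L),
      n_present = vapply(rows, `[[`, integer(1), 3L),
      p_printed = p)
  }
  r <- function(nova, n, n_present) as.integer(c(nova, n, n_present))
  dplyr::bind_rows(
    tbl("Milk, milk product, or milk substitute", "Milk", "n.a.",
        r(1, 94, 94), r(3, 6, 6), r(4, 71, 71)),
    tbl("Milk, milk product, or milk substitute", "Yogurt", "n.a.",
        r(1, 46, 46), r(4, 122, 122)),
    tbl("Milk, milk product, or milk substitute", "Cheese", "n.a.",
        r(3, 124, 124), r(4, 85, 85)),
    tbl("Milk, milk product, or milk substitute", "Milk substitute", "0.400",
        r(1, 6, 6), r(3, 37, 30), r(4, 291, 227)),
    tbl("Milk, milk product, or milk substitute", "Milk cream", "n.a.",
        r(4, 40, 40)),
    tbl("Milk, milk product, or milk substitute", "Dairy dessert", "n.a.",
        r(4, 43, 43)),
    tbl("Fresh or processed eggs", "Fresh or processed eggs", "n.a.",
        r(1, 34, 34), r(4, 1, 1)),
    tbl("Fresh or processed eggs", "Egg imitation", "n.a.", r(4, 1, 1)),
    tbl("Meat or related product", "Poultry meat", "n.a.", r(4, 2, 2)),
    tbl("Meat or related product", "Preserved meat", "0.013",
        r(1, 1, 1), r(3, 2, 0), r(4, 79, 65)),
    tbl("Meat or related product", "Sausage or similar meat", "n.a.",
        r(4, 37, 26)),
    tbl("Meat or related product", "Meat dish", "n.a.", r(4, 17, 16)),
    tbl("Meat or related product", "Meat analogue", "n.a.", r(4, 110, 89)),
    tbl("Seafood or related product", "Seafood product", "n.a.",
        r(3, 52, 52), r(4, 26, 26)),
    tbl("Fat or oil", "Vegetable fat or oil", "0.408",
        r(2, 1, 0), r(4, 7, 3)),
    tbl("Fat or oil", "Margarine or lipid of mixed origins", "n.a.",
        r(4, 39, 33)),
    tbl("Fat or oil", "Butter or other animal fat", "n.a.",
        r(2, 32, 32), r(4, 2, 2)),
    tbl("Grain or grain product", "Cereal or cereal-like milling products",
        "n.a.", r(4, 51, 51)),
    tbl("Grain or grain product", "Rice or similar products", "<0.01",
        r(1, 64, 8), r(3, 2, 0), r(4, 31, 28)),
    tbl("Grain or grain product", "Pasta and similar products", "0.082",
        r(1, 165, 163), r(3, 9, 9), r(4, 26, 24)),
    tbl("Grain or grain product", "Breakfast cereals", "0.983",
        r(1, 4, 4), r(3, 1, 1), r(4, 144, 143)),
    tbl("Grain or grain product", "Bread and similar products", "n.a.",
        r(4, 242, 241)),
    tbl("Grain or grain product", "Fine bakery ware", "n.a.", r(4, 279, 279)),
    tbl("Grain or grain product", "Savory cereal dish", "n.a.", r(4, 86, 86)),
    tbl("Nut, seed, or kernel", "Nuts", "n.a.",
        r(1, 20, 20), r(3, 14, 14), r(4, 31, 31)),
    tbl("Nut, seed, or kernel", "Seeds and kernels", "0.062",
        r(3, 18, 0), r(4, 17, 3)),
    tbl("Nut, seed, or kernel", "Nut or seed product", "n.a.",
        r(1, 9, 9), r(4, 18, 18)),
    tbl("Vegetable or vegetable product", "Vegetable (excluding potato)",
        "0.043", r(1, 65, 1), r(3, 35, 4), r(4, 70, 9)),
    tbl("Vegetable or vegetable product", "Starchy root or potato", "0.058",
        r(1, 1, 1), r(3, 2, 0), r(4, 18, 13)),
    tbl("Vegetable or vegetable product", "Pulse or pulse product", "n.a.",
        r(1, 341, 136)),
    tbl("Fruit or fruit product", "Processed fruit product", "0.078",
        r(1, 1, 1), r(3, 5, 0), r(4, 36, 16)),
    tbl("Sugar or sugar product", "Sugar, honey, or syrup", "n.a.",
        r(1, 1, 0), r(2, 35, 0), r(3, 6, 0), r(4, 4, 0)),
    tbl("Sugar or sugar product", "Jam or marmalade", "n.a.", r(4, 83, 17)),
    tbl("Sugar or sugar product",
        "Non-chocolate confectionery or other sugar product", "<0.01",
        r(3, 22, 10), r(4, 46, 45)),
    tbl("Sugar or sugar product", "Chocolate or chocolate product", "n.a.",
        r(4, 207, 207)),
    tbl("Beverage", "Juice or nectar", "<0.01",
        r(1, 48, 0), r(3, 1, 1), r(4, 114, 2)),
    tbl("Beverage", "Non-alcoholic beverage", "n.a.", r(4, 283, 17)),
    tbl("Miscellaneous food product", "Spice, condiment, or other ingredient",
        "0.009", r(1, 1, 0), r(2, 1, 1), r(3, 7, 2), r(4, 273, 208)),
    tbl("Miscellaneous food product", "Prepared food product", "n.a.",
        r(4, 164, 146)),
    tbl("Ready meals", "Ready to eat food", "n.a.", r(4, 38, 36)),
    tbl("Ready meals", "Frozen, semi-ready meal", "n.a.", r(4, 40, 20))
  )
}

#' Headline aggregate counts of the reference survey
#'
#' The published market-level aggregates: products analyzed after
#' exclusions, products declaring at least one allergen (any scope),
#' ultra-processed (NOVA4) products, NOVA4 products declaring at least one
#' allergen, and products declaring at least one trace. Also the sampling
#' frame: products collected, excluded for an unreadable ingredient list,
#' excluded for incomplete package imaging.
#'
#' @return A named list of integer counts.
#' @export
reference_survey_headlines <- function() {
  list(n_collected = 4851L, n_unreadable = 27L, n_incomplete = 237L,
       n_products = 4587L, n_any = 3301L, n_nova4 = 3275L,
       n_nova4_any = 2492L, n_nova1 = 901L, n_nova1_any = 523L,
       n_trace_any = 1781L)
}

# testability of a reference subcategory under the survey's n.a. rules
testable_subcategories <- function(counts = reference_survey_counts()) {
  counts |>
    dplyr::group_by(.data$category, .data$subcategory) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      degenerate = all(.data$n_present == .data$n) || all(.data$n_present == 0L),
      .groups = "drop") |>
    dplyr::mutate(testable = .data$n_groups >= 2L & !.data$degenerate)
}

#' Contingency tables for the testable reference subcategories
#'
#' Builds the NOVA-group by allergen-presence contingency tables for every
#' reference subcategory on which the chi-square comparison is applicable
#' (at least two NOVA groups, prevalence neither uniformly 100% nor 0%) -
#' 13 subcategories with the bundled data.
#'
#' @return A named list of `contingency_table` objects, in table order.
#' @export
reference_survey_tables <- function() {
  counts <- reference_survey_counts()
  keep <- testable_subcategories(counts)
  keep <- keep$subcategory[keep$testable]
  keep <- unique(counts$subcategory)[unique(counts$subcategory) %in% keep]
  out <- lapply(keep, function(sc) {
    sub <- counts[counts$subcategory == sc, ]
    new_contingency(
      tibble::tibble(nova = sub$nova, n_present = sub$n_present,
                     n_absent = sub$n - sub$n_present),
      subcategory = sc, scope = "any")
  })
  stats::setNames(out, keep)
}
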