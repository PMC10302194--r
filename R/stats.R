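#' Assemble the per-product analysis table
#'
#' Joins retained records, per-product allergen counts, and NOVA grades into
#' the single table the statistical layer works from.
#'
#' @param records Retained records tibble.
#' @param profiles Long profiles from [build_profiles()].
#' @param grades Grades tibble from [classify_all()].
#' @return A tibble with one row per product: taxonomy position, `nova`,
#'   `n_ingredient`, `n_trace`, `n_any`, `contains_any`.
#' @export
assemble_analysis <- function(records, profiles, grades) {
  counts <- profile_counts(profiles)
  out <- records |>
    dplyr::select("product_id", "category", "subcategory") |>
    dplyr::inner_join(counts, by = "product_id") |>
    dplyr::inner_join(grades[c("product_id", "nova")], by = "product_id")
  if (nrow(out) != nrow(records)) {
    stop("analysis inputs do not cover the same record set", call. = FALSE)
  }
  out
}

scope_count <- function(analysis, scope = c("any", "ingredient", "trace")) {
  scope <- match.arg(scope)
  switch(scope, any = analysis$n_any, ingredient = analysis$n_ingredient,
         trace = analysis$n_trace)
}

new_contingency <- function(df, subcategory, scope) {
  structure(tibble::as_tibble(df), subcategory = subcategory, scope = scope,
            class = c("contingency_table", class(tibble::tibble())))
}

#' Build a NOVA-group by allergen-presence contingency table
#'
#' One row per NOVA grade present in the subcategory (in grade order);
#' presence means the per-product allergen count for the requested scope is
#' at least one. Scope `"any"` (ingredient or trace) is the convention of
#' the bundled survey's prevalence table.
#'
#' @param analysis Output of [assemble_analysis()].
#' @param subcategory Subcategory name (must exist in the analysis table).
#' @param scope One of `"any"`, `"ingredient"`, `"trace"`.
#' @return A `contingency_table` tibble: `nova`, `n_present`, `n_absent`.
#' @export
build_contingency <- function(analysis, subcategory,
                              scope = c("any", "ingredient", "trace")) {
  scope <- match.arg(scope)
  if (!subcategory %in% analysis$subcategory) {
    stop("taxonomy error: no records for subcategory '", subcategory, "'",
         call. = FALSE)
  }
  sub <- analysis[analysis$subcategory == subcategory, ]
  k <- scope_count(sub, scope)
  df <- tibble::tibble(nova = sub$nova, present = k >= 1L) |>
    dplyr::group_by(.data$nova) |>
    dplyr::summarise(n_present = sum(.data$present),
                     n_absent = sum(!.data$present), .groups = "drop") |>
    dplyr::arrange(.data$nova)
  new_contingency(df, subcategory, scope)
}

#' Pearson chi-square test on a prevalence contingency table
#'
#' Pearson statistic (no continuity correction) over the grade x
#' presence/absence cells, df = rows - 1. The test is flagged not applicable
#' when only one NOVA group is present (`single_group`) or when prevalence
#' is uniformly 100% or uniformly 0% (`degenerate_prevalence`, which also
#' covers the zero-expected-cell case).
#'
#' @param tab A `contingency_table` (or tibble with `nova`, `n_present`,
#'   `n_absent`).
#' @return A `chisq_prevalence` list: `statistic`, `df`, `p_value`,
#'   `applicable`, `na_reason` (one of "none", "single_group",
#'   "degenerate_prevalence").
#' @export
pearson_chi_square <- function(tab) {
  stopifnot(all(c("nova", "n_present", "n_absent") %in% names(tab)))
  tab <- tab[tab$n_present + tab$n_absent > 0, ]
  res <- function(stat, df, p, reason) {
    structure(list(statistic = stat, df = df, p_value = p,
                   applicable = reason == "none", na_reason = reason,
                   subcategory = attr(tab, "subcategory")),
              class = "chisq_prevalence")
  }
  if (nrow(tab) < 2L) {
    return(res(NA_real_, NA_integer_, NA_real_, "single_group"))
  }
  prop <- tab$n_present / (tab$n_present + tab$n_absent)
  if (all(prop == 1) || all(prop == 0)) {
    return(res(NA_real_, NA_integer_, NA_real_, "degenerate_prevalence"))
  }
  m <- as.matrix(tab[c("n_present", "n_absent")])
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  res(unname(ct$statistic), unname(ct$parameter), unname(ct$p.value), "none")
}

#' @export
print.chisq_prevalence <- function(x, ...) {
  if (x$applicable) {
    cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %s\n",
                x$statistic, x$df, format_p(x$p_value)))
  } else {
    cat(sprintf("Pearson chi-square: not applicable (%s)\n", x$na_reason))
  }
  invisible(x)
}

#' Per-subcategory prevalence report with chi-square tests
#'
#' The survey-table-shaped report: for every subcategory, the per-grade
#' group size, number and percentage of products with at least one allergen
#' in the given scope, and the Pearson chi-square p-value across grades
#' (rendered "n.a." where not applicable; "<0.01" below the rendering
#' threshold). Applicability is always judged on the scope `"any"` table,
#' mirroring the reference survey.
#'
#' @inheritParams build_contingency
#' @param alpha Significance level (default 0.01).
#' @return A tibble with one row per subcategory x grade: `category`,
#'   `subcategory`, `nova`, `n`, `n_present`, `pct`, `pct_label`,
#'   `statistic`, `p_value`, `p_label`, `applicable`, `na_reason`,
#'   `significant`. Attributes: `alpha`, `n_testable`, `n_significant`.
#' @export
prevalence_report <- function(analysis, alpha = 0.01,
                              scope = c("any", "ingredient", "trace")) {
  scope <- match.arg(scope)
  subcats <- unique(analysis$subcategory)
  rows <- lapply(subcats, function(sc) {
    tab <- build_contingency(analysis, sc, scope)
    na_tab <- if (scope == "any") tab else build_contingency(analysis, sc, "any")
    applicability <- pearson_chi_square(na_tab)
    ct <- if (applicability$applicable) pearson_chi_square(tab) else applicability
    tibble::tibble(
      category = analysis$category[match(sc, analysis$subcategory)],
      subcategory = sc,
      nova = tab$nova,
      n = tab$n_present + tab$n_absent,
      n_present = tab$n_present,
      pct = round_half_up(100 * tab$n_present / (tab$n_present + tab$n_absent), 1),
      pct_label = format_pct(tab$n_present, tab$n_present + tab$n_absent),
      statistic = ct$statistic,
      p_value = ct$p_value,
      p_label = format_p(ct$p_value),
      applicable = ct$applicable,
      na_reason = ct$na_reason,
      significant = ct$applicable & !is.na(ct$p_value) & ct$p_value < alpha
    )
  })
  out <- dplyr::bind_rows(rows)
  per_sub <- out[!duplicated(out$subcategory), ]
  attr(out, "alpha") <- alpha
  attr(out, "n_testable") <- sum(per_sub$applicable)
  attr(out, "n_significant") <- sum(per_sub$significant)
  out
}

#' Allergen-count distribution and means per NOVA group
#'
#' For the requested scope, per grade: group size, number of declaring
#' products, prevalence, the count histogram, and both mean conventions -
#' `mean_over_all` (sum of counts over all products in the grade) and
#' `mean_over_declaring` (over products declaring at least one; NA when no
#' product declares). The reporting layer uses `mean_over_all` for scopes
#' any/ingredient and `mean_over_declaring` for scope trace.
#'
#' @inheritParams build_contingency
#' @return A tibble with one row per grade present: `nova`, `n_foods`,
#'   `n_declaring`, `prevalence_pct`, `mean_over_all`,
#'   `mean_over_declaring`, `histogram` (list-column of tibbles `k`, `n`).
#' @export
count_summary <- function(analysis, scope = c("any", "ingredient", "trace")) {
  scope <- match.arg(scope)
  k <- scope_count(analysis, scope)
  tibble::tibble(nova = analysis$nova, k = k) |>
    dplyr::group_by(.data$nova) |>
    dplyr::summarise(
      n_foods = dplyr::n(),
      n_declaring = sum(.data$k >= 1L),
      prevalence_pct = round_half_up(100 * sum(.data$k >= 1L) / dplyr::n(), 1),
      mean_over_all = mean(.data$k),
      mean_over_declaring = ifelse(any(.data$k >= 1L),
                                   mean(.data$k[.data$k >= 1L]), NA_real_),
      histogram = list({
        tab <- table(.data$k)
        tibble::tibble(k = as.integer(names(tab)), n = as.integer(tab))
      }),
      .groups = "drop") |>
    dplyr::arrange(.data$nova)
}

#' Distinct-allergen diversity per subcategory, grade, and scope
#'
#' Reports the set of distinct allergens observed across all products of
#' each (subcategory, NOVA grade) cell under the given scope. With
#' `pool_nova123`, grades 1-3 are additionally merged into a single
#' less-processed comparator, and each subcategory having both a NOVA4 cell
#' and a pooled cell is flagged for whether the NOVA4 set is strictly larger.
#'
#' @param profiles Long profiles from [build_profiles()].
#' @param analysis Output of [assemble_analysis()].
#' @inheritParams build_contingency
#' @param pool_nova123 Also compute the pooled NOVA1-3 comparator.
#' @return A list with `cells` (tibble: `subcategory`, `group`, `allergens`
#'   list-column, `n_allergens`) and, when pooling, `comparison` (tibble:
#'   `subcategory`, `n_nova4`, `n_nova123`, `nova4_strictly_larger`).
#' @export
diversity_report <- function(profiles, analysis,
                             scope = c("any", "ingredient", "trace"),
                             pool_nova123 = TRUE) {
  scope <- match.arg(scope)
  keep_status <- switch(scope, any = c("ingredient", "trace"),
                        ingredient = "ingredient", trace = "trace")
  long <- profiles |>
    dplyr::filter(.data$status %in% keep_status) |>
    dplyr::inner_join(analysis[c("product_id", "subcategory", "nova")],
                      by = "product_id")
  cell_sets <- function(df, label_col) {
    df |>
      dplyr::group_by(.data$subcategory, group = .data[[label_col]]) |>
      dplyr::summarise(
        allergens = list(sort(unique(as.character(.data$allergen)))),
        .groups = "drop") |>
      dplyr::mutate(n_allergens = lengths(.data$allergens))
  }
  long$grade_label <- paste0("NOVA", long$nova)
  cells <- cell_sets(long, "grade_label")
  # carry empty cells for grades present in the analysis but with no hits
  frame <- analysis |>
    dplyr::distinct(.data$subcategory, group = paste0("NOVA", .data$nova))
  cells <- frame |>
    dplyr::left_join(cells, by = c("subcategory", "group")) |>
    dplyr::mutate(
      allergens = lapply(.data$allergens, function(a) a %||% character(0)),
      n_allergens = lengths(.data$allergens))
  out <- list(cells = cells)
  if (pool_nova123) {
    long$pool_label <- ifelse(long$nova == 4L, "NOVA4", "NOVA1-3")
    frame_pool <- analysis |>
      dplyr::distinct(.data$subcategory,
                      group = ifelse(.data$nova == 4L, "NOVA4", "NOVA1-3"))
    pooled <- frame_pool |>
      dplyr::left_join(cell_sets(long, "pool_label"),
                       by = c("subcategory", "group")) |>
      dplyr::mutate(
        allergens = lapply(.data$allergens, function(a) a %||% character(0)),
        n_allergens = lengths(.data$allergens))
    cmp <- pooled |>
      dplyr::select("subcategory", "group", "n_allergens") |>
      tidyr::pivot_wider(names_from = "group", values_from = "n_allergens")
    if (all(c("NOVA4", "NOVA1-3") %in% names(cmp))) {
      cmp <- cmp |>
        dplyr::filter(!is.na(.data$`NOVA4`), !is.na(.data$`NOVA1-3`)) |>
        dplyr::transmute(.data$subcategory, n_nova4 = .data$`NOVA4`,
                         n_nova123 = .data$`NOVA1-3`,
                         nova4_strictly_larger = .data$n_nova4 > .data$n_nova123)
    } else {
      cmp <- tibble::tibble(subcategory = character(), n_nova4 = integer(),
                            n_nova123 = integer(),
                            nova4_strictly_larger = logical())
    }
    out$pooled <- pooled
    out$comparison <- cmp
  }
  out
}
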