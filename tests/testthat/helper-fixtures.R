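# shared fixtures built in code; lexicons loaded once per test run
lex <- load_allergen_lexicon()
lex_el <- load_allergen_lexicon(
  system.file("extdata", "allergen_lexicon_el.json", package = "allergenova"))
markers <- load_marker_lexicon()
taxonomy <- default_taxonomy()

# a small hand-written record set spanning the exclusion cases
make_records <- function(n = 3) {
  base <- tibble::tibble(
    product_id = sprintf("P%03d", seq_len(n)),
    name = paste("item", seq_len(n)),
    category = "Vegetable or vegetable product",
    subcategory = "Pulse or pulse product",
    ingredient_text = "lentils",
    precaution_texts = replicate(n, character(0), simplify = FALSE),
    ingredient_list_readable = TRUE,
    all_package_sides_available = TRUE)
  validate_records(base, taxonomy)
}

# flag-driven record set: counts of unreadable / incomplete / both
make_flagged_records <- function(n, n_unreadable, n_incomplete, n_both = 0) {
  rs <- make_records(n)
  rs$ingredient_list_readable[seq_len(n_unreadable + n_both)] <- FALSE
  rs$ingredient_text[seq_len(n_unreadable + n_both)] <- NA_character_
  rs$all_package_sides_available[
    n_unreadable + seq_len(n_incomplete + n_both)] <- FALSE
  rs
}

# scaled-down synthetic configuration (same structure, fewer records)
scaled_config <- function(seed = 11, scale = 0.1, ...) {
  cfg <- synthetic_config(seed = seed, ...)
  n <- cfg$n_per_subcategory
  cfg$n_per_subcategory <- stats::setNames(
    pmax(1L, as.integer(round(n * scale))), names(n))
  cfg
}

# exact recovery measurement against generator ground truth
measure_recovery <- function(gen, profiles, grades) {
  truth <- gen$truth[match(grades$product_id, gen$truth$product_id), ]
  per_status <- function(status, truth_col) {
    tp <- fp <- fn <- 0L
    for (i in seq_len(nrow(truth))) {
      det <- as.character(
        profiles$allergen[profiles$product_id == truth$product_id[i] &
                            profiles$status == status])
      tru <- truth[[truth_col]][[i]]
      tp <- tp + length(intersect(det, tru))
      fp <- fp + length(setdiff(det, tru))
      fn <- fn + length(setdiff(tru, det))
    }
    if (tp + fp + fn == 0L) return(1)
    precision <- if (tp + fp) tp / (tp + fp) else 1
    recall <- if (tp + fn) tp / (tp + fn) else 1
    2 * precision * recall / (precision + recall)
  }
  list(
    nova_accuracy = mean(grades$nova == truth$grade),
    f1_ingredient = per_status("ingredient", "ingredient_allergens"),
    f1_trace = per_status("trace", "trace_allergens"))
}

# independent 2x2 closed form: n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
chisq_2x2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
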