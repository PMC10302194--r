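# rendering vocabularies for the generator; all terms are lexicon-conformant
# (canonical or derivative) and none collide with culinary or marker terms,
# so ground truth is recoverable exactly when out_of_lexicon_rate = 0
syn_base_foods <- c("lentils", "tomatoes", "chickpeas", "carrots", "spinach",
                    "mushrooms", "green peas", "apricots", "brown rice",
                    "red beans", "zucchini", "cauliflower")
syn_culinary <- c("salt", "sugar", "olive oil", "sunflower oil",
                  "corn starch", "honey")
syn_markers <- c("flavourings",
                 "emulsifier: mono- and diglycerides of fatty acids (e471)",
                 "thickener: guar gum (e412)",
                 "antioxidant: ascorbic acid (e300)",
                 "sweetener: sucralose (e955)",
                 "flavour enhancer: monosodium glutamate (e621)",
                 "pea protein isolate",
                 "bulking agent: polydextrose")
syn_ingredient_terms <- list(
  gluten_cereals = c("wheat flour", "spelt"),
  crustaceans = c("shrimp", "prawns"),
  eggs = c("eggs", "egg yolk"),
  fish = c("fish", "anchovies"),
  peanuts = c("peanuts", "groundnuts"),
  soybeans = c("soybeans", "tofu"),
  milk = c("milk", "whey powder"),
  tree_nuts = c("hazelnuts", "almonds"),
  celery = c("celery", "celeriac"),
  mustard = c("mustard", "mustard flour"),
  sesame = c("sesame seeds", "tahini"),
  sulphites = c("sulphites", "e224"),
  lupin = c("lupin", "lupin flour"),
  mollusks = c("mussels", "squid"))
syn_trace_terms <- list(
  gluten_cereals = c("gluten", "barley"),
  crustaceans = c("crustaceans", "prawns"),
  eggs = c("eggs", "egg"),
  fish = c("fish", "anchovies"),
  peanuts = c("peanuts", "groundnuts"),
  soybeans = c("soya", "soy"),
  milk = c("milk", "whey"),
  tree_nuts = c("nuts", "hazelnuts"),
  celery = c("celery", "celeriac"),
  mustard = c("mustard", "mustard seed"),
  sesame = c("sesame", "tahini"),
  sulphites = c("sulphites", "sulphur dioxide"),
  lupin = c("lupin", "lupine"),
  mollusks = c("molluscs", "mussels"))
# adversarial vocabulary absent from the shipped lexicon
syn_out_of_lexicon <- c(
  gluten_cereals = "triticum blend", crustaceans = "scampi bits",
  eggs = "ovoproduct", fish = "marine collagen", peanuts = "arachide",
  soybeans = "glycine max", milk = "dairy solids",
  tree_nuts = "filbert pieces", celery = "apium", mustard = "sinapis",
  sesame = "benne", sulphites = "sulphurous agent",
  lupin = "lupinus seed", mollusks = "calamari")
syn_marker_ool <- "proprietary texturiser blend"

default_grade_mixture <- function(counts = reference_survey_counts()) {
  split(counts, counts$subcategory) |>
    lapply(function(sub) {
      p <- stats::setNames(numeric(4), 1:4)
      p[as.character(sub$nova)] <- sub$n / sum(sub$n)
      p
    })
}

default_rate_matrix <- function(p_any_by_grade) {
  r <- 1 - (1 - p_any_by_grade)^(1 / 14)
  m <- matrix(rep(r, each = 14), nrow = 4, ncol = 14, byrow = TRUE,
              dimnames = list(1:4, eu_allergens()))
  m
}

#' Configuration for the synthetic label generator
#'
#' Defaults emulate the reference survey's structure: per-subcategory record
#' counts and NOVA-grade mixtures come from the bundled reference counts;
#' per-grade allergen rates are calibrated so that the chance of at least
#' one allergen (14 independent per-allergen draws) matches the survey's
#' per-grade ingredient and trace prevalences; exclusion-flag rates match
#' the survey's sampling frame (27/4851 unreadable, 237/4851 incomplete).
#'
#' @param seed Integer seed; with the per-record hashing scheme it fully
#'   determines the output.
#' @param n_per_subcategory Named integer vector (subcategory -> count).
#' @param grade_mixture Named list: subcategory -> probability vector over
#'   grades 1-4 (must sum to 1).
#' @param ingredient_rates,trace_rates 4 x 14 matrices (grade x allergen) of
#'   per-allergen declaration probabilities.
#' @param synonym_rate Probability of rendering an allergen with a
#'   derivative term instead of its canonical term.
#' @param out_of_lexicon_rate Probability of rendering a term (allergen or
#'   ultra-processing marker) with vocabulary absent from the lexicon
#'   (adversarial mode; ground truth then exceeds what is detectable).
#' @param trigger_weights Named weights over precautionary trigger-phrase
#'   variants.
#' @param exclusion_rates Named vector with `unreadable` and `incomplete`
#'   probabilities.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_per_subcategory = NULL,
                             grade_mixture = NULL,
                             ingredient_rates = NULL,
                             trace_rates = NULL,
                             synonym_rate = 0.3,
                             out_of_lexicon_rate = 0,
                             trigger_weights = c(
                               "may contain traces of" = 0.6,
                               "may contain" = 0.25,
                               "manufactured in a facility that also processes" = 0.15),
                             exclusion_rates = c(unreadable = 27 / 4851,
                                                 incomplete = 237 / 4851)) {
  counts <- reference_survey_counts()
  if (is.null(n_per_subcategory)) {
    n_per_subcategory <- counts |>
      dplyr::group_by(.data$subcategory) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      (\(d) stats::setNames(d$n, d$subcategory))()
  }
  cfg <- list(
    seed = as.integer(seed),
    n_per_subcategory = n_per_subcategory,
    grade_mixture = grade_mixture %||% default_grade_mixture(counts),
    ingredient_rates = ingredient_rates %||%
      default_rate_matrix(c(0.417, 0.478, 0.675, 0.708)),
    trace_rates = trace_rates %||%
      default_rate_matrix(c(0.287, 0.014, 0.102, 0.454)),
    synonym_rate = synonym_rate,
    out_of_lexicon_rate = out_of_lexicon_rate,
    trigger_weights = trigger_weights,
    exclusion_rates = exclusion_rates)
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg, taxonomy = default_taxonomy()) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  unknown <- setdiff(names(cfg$n_per_subcategory), taxonomy$subcategory)
  if (length(unknown)) {
    stop("synthetic config error: subcategories not in taxonomy: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  probs <- c(cfg$synonym_rate, cfg$out_of_lexicon_rate, cfg$exclusion_rates,
             cfg$ingredient_rates, cfg$trace_rates)
  if (any(probs < 0 | probs > 1)) {
    stop("synthetic config error: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  for (sc in names(cfg$n_per_subcategory)) {
    mix <- cfg$grade_mixture[[sc]]
    if (is.null(mix) || length(mix) != 4L || abs(sum(mix) - 1) > 1e-8) {
      stop("synthetic config error: grade mixture for '", sc,
           "' must be a length-4 probability vector summing to 1",
           call. = FALSE)
    }
  }
  stopifnot(all(c("unreadable", "incomplete") %in% names(cfg$exclusion_rates)))
  structure(cfg, class = "synthetic_config")
}

sample_weighted <- function(x, weights = NULL) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = weights)]
}

render_record <- function(product_id, subcategory, category, cfg) {
  # per-record substream: the draw sequence depends only on the product id
  # and the configured seed, never on record order
  record_seed <- ((as.double(cfg$seed) %% 2147483647) * 2047 +
                    string_hash(product_id)) %% 2147483647
  set.seed(as.integer(record_seed))
  grade <- sample.int(4L, 1L, prob = cfg$grade_mixture[[subcategory]])
  ool <- function() stats::runif(1) < cfg$out_of_lexicon_rate
  syn <- function() stats::runif(1) < cfg$synonym_rate

  ids <- eu_allergens()
  ing_set <- ids[stats::runif(14) < cfg$ingredient_rates[grade, ids]]
  trace_set <- ids[stats::runif(14) < cfg$trace_rates[grade, ids]]
  trace_set <- setdiff(trace_set, ing_set) # ingredient precedence, once

  pick_term <- function(id, pool) {
    if (ool()) return(syn_out_of_lexicon[[id]])
    pool[[id]][[if (syn() && length(pool[[id]]) > 1L) 2L else 1L]]
  }

  n_base <- switch(grade, sample(1:3, 1L), 0L, sample(1:2, 1L), sample(1:2, 1L))
  bases <- if (n_base > 0) sample(syn_base_foods, n_base) else character(0)
  culinary <- switch(grade,
                     character(0),
                     sample_weighted(syn_culinary),
                     sample_weighted(syn_culinary),
                     if (stats::runif(1) < 0.5) sample_weighted(syn_culinary) else character(0))
  markers <- if (grade == 4L) {
    m <- sample(syn_markers, sample(1:2, 1L))
    vapply(m, function(x) if (ool()) syn_marker_ool else x, character(1),
           USE.NAMES = FALSE)
  } else character(0)
  water <- if (grade %in% 3:4 && stats::runif(1) < 0.3) "water" else character(0)

  ing_terms <- vapply(ing_set, pick_term, character(1),
                      pool = syn_ingredient_terms, USE.NAMES = FALSE)
  precaution_texts <- character(0)
  if (grade == 2L) {
    # a single-ingredient culinary product declares allergens via a
    # post-list "contains" statement rather than extra ingredient phrases
    phrases <- culinary
    if (length(ing_terms)) {
      precaution_texts <- paste("contains", paste(ing_terms, collapse = ", "))
    }
  } else {
    phrases <- c(bases, ing_terms, culinary, markers, water)
  }
  if (length(trace_set)) {
    trigger <- sample_weighted(names(cfg$trigger_weights), cfg$trigger_weights)
    tr_terms <- vapply(trace_set, pick_term, character(1),
                       pool = syn_trace_terms, USE.NAMES = FALSE)
    precaution_texts <- c(precaution_texts,
                          paste(trigger, paste(tr_terms, collapse = ", ")))
  }
  unreadable <- stats::runif(1) < cfg$exclusion_rates[["unreadable"]]
  incomplete <- stats::runif(1) < cfg$exclusion_rates[["incomplete"]]

  list(
    record = tibble::tibble(
      product_id = product_id,
      name = paste("sample item", product_id),
      category = category,
      subcategory = subcategory,
      ingredient_text = if (unreadable) NA_character_ else
        paste(phrases, collapse = ", "),
      precaution_texts = list(if (incomplete) character(0) else precaution_texts),
      ingredient_list_readable = !unreadable,
      all_package_sides_available = !incomplete),
    truth = tibble::tibble(
      product_id = product_id,
      subcategory = subcategory,
      grade = as.integer(grade),
      ingredient_allergens = list(ing_set),
      trace_allergens = list(trace_set),
      unreadable = unreadable,
      incomplete = incomplete))
}

#' Generate a synthetic branded-food record set with ground truth
#'
#' Ground truth (NOVA grade, allergen sets, exclusion flags) is drawn first
#' and label text is then rendered to realize it: grade-4 records embed at
#' least one ultra-processing marker phrase, grade-3 records a culinary term
#' inside a multi-ingredient list, grade-2 records a single culinary
#' ingredient (with allergens declared via a "contains" statement), and
#' grade-1 records neither markers nor culinary terms. Allergens are
#' rendered as canonical or derivative lexicon terms (per `synonym_rate`)
#' and traces with weighted trigger-phrase variants. The same seed yields
#' byte-identical output regardless of generation order.
#'
#' @param config A [synthetic_config()].
#' @param taxonomy Taxonomy the subcategories must belong to.
#' @return A list with `records` (validated tibble) and `truth` (tibble:
#'   `product_id`, `subcategory`, `grade`, `ingredient_allergens`,
#'   `trace_allergens`, `unreadable`, `incomplete`).
#' @export
generate_labels <- function(config, taxonomy = default_taxonomy()) {
  config <- validate_synthetic_config(config, taxonomy)
  subcats <- names(config$n_per_subcategory)
  parent <- stats::setNames(taxonomy$category, taxonomy$subcategory)
  idx <- 0L
  out <- vector("list", sum(config$n_per_subcategory))
  for (sc in subcats) {
    for (i in seq_len(config$n_per_subcategory[[sc]])) {
      idx <- idx + 1L
      out[[idx]] <- render_record(sprintf("SYN-%05d", idx), sc, parent[[sc]],
                                  config)
    }
  }
  records <- dplyr::bind_rows(lapply(out, `[[`, "record"))
  truth <- dplyr::bind_rows(lapply(out, `[[`, "truth"))
  records <- validate_records(records, taxonomy)
  attr(records, "provenance") <- sprintf("synthetic(seed=%d)", config$seed)
  list(records = records, truth = truth)
}
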