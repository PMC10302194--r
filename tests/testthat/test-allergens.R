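test_that("the lexicon validates its shape on load", {
  expect_length(eu_allergens(), 14L)
  expect_s3_class(lex, "allergen_lexicon")
  expect_setequal(names(lex$allergens), eu_allergens())
  expect_true(all(vapply(lex$allergens,
                         function(a) length(a$canonical_terms) >= 1, logical(1))))
})

test_that("ingredient-scope detection matches canonical and derivative terms", {
  phrases <- split_ingredient_list(normalize_text(
    "wheat flour, sugar, hazelnuts, skimmed milk powder, whey powder, emulsifier: lecithins (soy)"))
  found <- detect_ingredient_allergens(phrases, lexicon = lex)
  expect_setequal(found, c("gluten_cereals", "tree_nuts", "milk", "soybeans"))

  expect_length(detect_ingredient_allergens(c("water", "salt"), lexicon = lex), 0L)

  # E-numbers in the sulphite range count; neighbours do not
  for (e in c("e220", "e224", "e228")) {
    expect_true("sulphites" %in% detect_ingredient_allergens(
      c("dried apricots", e), lexicon = lex), info = e)
  }
  expect_false("sulphites" %in% detect_ingredient_allergens(
    c("dried apricots", "e229"), lexicon = lex))
})

test_that("free-from claims suppress only the claimed term and are logged", {
  found <- detect_ingredient_allergens(
    split_ingredient_list(normalize_text("gluten-free oat flakes")),
    lexicon = lex)
  expect_equal(as.character(found), "gluten_cereals") # oat derivative remains
  claims <- attr(found, "claims")
  expect_equal(claims$allergen, "gluten_cereals")
  expect_match(claims$pattern, "gluten")

  none <- detect_ingredient_allergens(
    split_ingredient_list(normalize_text("lactose-free drink, stabiliser")),
    lexicon = lex)
  expect_false("milk" %in% none)
})

test_that("precautionary statements require a trigger and map to traces", {
  expect_setequal(
    detect_precautionary_allergens("may contain traces of nuts and sesame", lex),
    c("tree_nuts", "sesame"))
  expect_equal(
    detect_precautionary_allergens(
      "manufactured in a facility that also processes peanuts", lex),
    "peanuts")
  expect_length(detect_precautionary_allergens(character(0), lex), 0L)
  # a plain description without trigger phrase is not a trace declaration
  expect_length(detect_precautionary_allergens("store in a cool place", lex), 0L)
  expect_warning(
    detect_precautionary_allergens("may contain traces of stardust", lex),
    "no recognizable allergen")
})

test_that("profiles apply ingredient-over-trace precedence and count scopes", {
  rec <- list(ingredient_text = "milk",
              precaution_texts = c("may contain traces of milk and nuts"))
  p <- build_profile(rec, lex)
  expect_equal(unname(p$statuses["milk"]), "ingredient")
  expect_equal(unname(p$statuses["tree_nuts"]), "trace")
  expect_equal(p$n_ingredient, 1L)
  expect_equal(p$n_trace, 1L)
  expect_equal(p$n_any, 2L)
  expect_true(p$contains_any)

  # post-list "contains" statements are ingredient declarations
  rec2 <- list(ingredient_text = "sunflower oil",
               precaution_texts = c("contains sulphites"))
  p2 <- build_profile(rec2, lex)
  expect_equal(unname(p2$statuses["sulphites"]), "ingredient")

  empty <- build_profile(list(ingredient_text = "water, salt",
                              precaution_texts = character(0)), lex)
  expect_false(empty$contains_any)
  expect_equal(empty$n_any, 0L)

  all14 <- build_profile(list(
    ingredient_text = paste(
      "wheat flour, shrimp, eggs, fish, peanuts, soybeans, milk, hazelnuts,",
      "celery, mustard, sesame seeds, sulphites, lupin, mussels"),
    precaution_texts = character(0)), lex)
  expect_equal(all14$n_ingredient, 14L)
  expect_equal(all14$n_trace, 0L)
})

test_that("adding phrases never removes a detected allergen (monotonicity)", {
  base_lists <- list(
    c("milk", "sugar"),
    c("wheat flour", "hazelnuts (13%)"),
    c("gluten-free oat flakes"),
    c("emulsifier: lecithins (soy)", "salt"))
  extra <- c("tomato paste", "mustard", "e221", "natural flavour", "peanuts")
  for (bl in base_lists) {
    before <- detect_ingredient_allergens(normalize_text(bl), lexicon = lex)
    for (e in extra) {
      after <- detect_ingredient_allergens(normalize_text(c(bl, e)), lexicon = lex)
      expect_true(all(before %in% after),
                  info = paste(paste(bl, collapse = "+"), "->", e))
    }
  }
})

test_that("the Greek lexicon detects accent-varied Greek label text", {
  found <- detect_ingredient_allergens(
    split_ingredient_list(normalize_text("αλεύρι σιταριού, λεκιθίνη σόγιας")),
    lexicon = lex_el)
  expect_setequal(found, c("gluten_cereals", "soybeans"))
  expect_equal(
    detect_precautionary_allergens("μπορεί να περιέχει ίχνη σουσάμι", lex_el),
    "sesame")
})

test_that("identical inputs yield identical profiles (determinism)", {
  rec <- list(ingredient_text = "milk, hazelnuts (13%), emulsifier: lecithins (soy)",
              precaution_texts = "may contain traces of sesame")
  expect_identical(build_profile(rec, lex), build_profile(rec, lex))
})
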