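test_that("the generator is seed-deterministic and order-independent", {
  cfg <- scaled_config(seed = 7, scale = 0.03)
  g1 <- generate_labels(cfg)
  g2 <- generate_labels(cfg)
  expect_identical(g1$records$ingredient_text, g2$records$ingredient_text)
  expect_identical(g1$records$precaution_texts, g2$records$precaution_texts)
  expect_identical(g1$truth$grade, g2$truth$grade)

  g3 <- generate_labels(scaled_config(seed = 8, scale = 0.03))
  expect_false(identical(g1$records$ingredient_text, g3$records$ingredient_text))

  # per-record substreams: a record's draws do not depend on its neighbours
  cfg_one <- cfg
  cfg_one$n_per_subcategory <- cfg$n_per_subcategory[1]
  alone <- generate_labels(cfg_one)
  expect_identical(
    alone$records$ingredient_text,
    g1$records$ingredient_text[g1$records$subcategory ==
                                 names(cfg_one$n_per_subcategory)])
})

test_that("a null configuration yields empty profiles and grade 1 throughout", {
  cfg <- synthetic_config(
    seed = 1,
    n_per_subcategory = c("Pulse or pulse product" = 10L),
    grade_mixture = list("Pulse or pulse product" = c(1, 0, 0, 0)),
    ingredient_rates = matrix(0, 4, 14, dimnames = list(1:4, eu_allergens())),
    trace_rates = matrix(0, 4, 14, dimnames = list(1:4, eu_allergens())),
    exclusion_rates = c(unreadable = 0, incomplete = 0))
  gen <- generate_labels(cfg)
  expect_equal(nrow(gen$records), 10L)
  profiles <- build_profiles(gen$records, lex)
  expect_true(all(profiles$status == "absent"))
  grades <- classify_all(gen$records, markers)
  expect_true(all(grades$nova == 1L))
})

test_that("ground truth is recovered exactly on lexicon-conformant data", {
  gen <- generate_labels(scaled_config(seed = 11, scale = 0.1))
  retained <- apply_exclusions(gen$records)$retained
  profiles <- build_profiles(retained, lex)
  grades <- classify_all(retained, markers)
  rec <- measure_recovery(gen, profiles, grades)
  expect_equal(rec$nova_accuracy, 1.0)
  expect_equal(rec$f1_ingredient, 1.0)
  expect_equal(rec$f1_trace, 1.0)
})

test_that("out-of-lexicon vocabulary degrades grade-4 recall gracefully", {
  cfg <- scaled_config(seed = 13, scale = 0.05, out_of_lexicon_rate = 0.5)
  gen <- generate_labels(cfg)
  retained <- apply_exclusions(gen$records)$retained
  grades <- classify_all(retained, markers)
  truth <- gen$truth[match(retained$product_id, gen$truth$product_id), ]
  g4 <- truth$grade == 4L
  recall4 <- mean(grades$nova[g4] == 4L)
  expect_lt(recall4, 1.0)
  expect_gt(recall4, 0.2)
  # non-grade-4 records are never promoted by missing vocabulary
  expect_true(all(grades$nova[!g4] == truth$grade[!g4]))
})

test_that("configured rates surface as empirical prevalence", {
  ids <- eu_allergens()
  rates <- matrix(0, 4, 14, dimnames = list(1:4, ids))
  rates[, "milk"] <- 1 # every product declares milk as an ingredient
  cfg <- synthetic_config(
    seed = 2,
    n_per_subcategory = c("Milk" = 60L),
    grade_mixture = list("Milk" = c(0.5, 0, 0.2, 0.3)),
    ingredient_rates = rates,
    trace_rates = matrix(0, 4, 14, dimnames = list(1:4, ids)),
    exclusion_rates = c(unreadable = 0, incomplete = 0))
  gen <- generate_labels(cfg)
  profiles <- build_profiles(gen$records, lex)
  counts <- profile_counts(profiles)
  expect_true(all(counts$n_ingredient >= 1L))
  milk <- profiles[profiles$allergen == "milk", ]
  expect_true(all(milk$status == "ingredient"))

  # binomial convergence of a fractional rate
  rates[, "milk"] <- 0.4
  cfg$ingredient_rates <- rates
  cfg$n_per_subcategory <- c("Milk" = 400L)
  gen2 <- generate_labels(cfg)
  has_milk <- vapply(gen2$truth$ingredient_allergens,
                     function(a) "milk" %in% a, logical(1))
  p_hat <- mean(has_milk)
  expect_lt(abs(p_hat - 0.4), 3 * sqrt(0.4 * 0.6 / 400))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(seed = 1, n_per_subcategory = c("Nope" = 5L)),
               "not in taxonomy")
  expect_error(synthetic_config(seed = 1, synonym_rate = 1.5), "\\[0, 1\\]")
  expect_error(
    synthetic_config(seed = 1,
                     n_per_subcategory = c("Milk" = 5L),
                     grade_mixture = list("Milk" = c(0.5, 0.5, 0.5, 0))),
    "summing to 1")
})

test_that("the bundled reference counts are internally coherent", {
  counts <- reference_survey_counts()
  expect_equal(length(unique(counts$subcategory)), 41L)
  expect_equal(length(unique(counts$category)), 13L)
  expect_true(all(counts$n_present <= counts$n))
  expect_setequal(unique(counts$subcategory), taxonomy$subcategory)
  # grade rows sum exactly to the analyzable set (only the source's
  # subcategory/category header totals are inconsistent; headers are not
  # shipped)
  expect_equal(sum(counts$n), 4587L)
  # NOVA1 margins: 901 products; the summed present count is 524, one more
  # than the published headline count of 523 (another source-table quirk)
  n1 <- counts[counts$nova == 1L, ]
  expect_equal(sum(n1$n), 901L)
  expect_equal(sum(n1$n_present), 524L)
})
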