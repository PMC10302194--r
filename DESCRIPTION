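Package: allergenova
Title: Allergen Declarations and NOVA Processing Grades in Branded Food Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based analysis of packaged-food label data: detection of the
    14 EU-regulated allergens in free-text ingredient lists (declared as an
    ingredient) and in precautionary "may contain" statements (declared as a
    trace), assignment of NOVA food-processing grades 1-4 from the ingredient
    list via a marker lexicon, and the associated prevalence statistics
    (per-subcategory NOVA-group by allergen-presence contingency tables with
    Pearson chi-square tests, allergen-count distributions per grade, and
    allergen-diversity comparisons). Includes a seeded synthetic label
    generator with ground truth for end-to-end recovery testing, and a
    bundled reference prevalence table from a Greek branded-food market
    survey.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
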