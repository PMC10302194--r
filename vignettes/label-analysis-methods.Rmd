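---
title: "Methods: allergen declarations and NOVA grades in branded-food labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allergen declarations and NOVA grades in branded-food labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analytical problem

Packaged foods carry two kinds of allergen information on their labels: the
ingredient list, where any of the 14 EU-regulated allergens (gluten-containing
cereals, crustaceans, eggs, fish, peanuts, soybeans, milk, tree nuts, celery,
mustard, sesame, sulphites, lupin, and mollusks) must be declared when used as
an ingredient, and voluntary precautionary statements ("may contain traces
of ...") warning of adventitious presence through cross-contamination. The
same ingredient list also carries the evidence needed to grade a food's degree
of processing under the NOVA scheme (1 = unprocessed or minimally processed,
2 = culinary ingredient, 3 = processed, 4 = ultra-processed), because
ultra-processing leaves characteristic marks: additives, flavourings,
isolates, extracts, and other substances rarely used in domestic kitchens.

`allergenova` implements this whole chain as a reproducible pipeline over
tabular branded-food records: completeness filtering, rule-based allergen
detection in two scopes, rule-based NOVA grading, and the prevalence
statistics that compare allergen presence across NOVA groups within food
subcategories. Because the branded-food databases such analyses are run on
are typically access-gated, the package also ships a seeded synthetic label
generator with full ground truth, so every stage is testable end to end
without external data.

## Record model and exclusions

A record is one packaged product: an opaque `product_id`, a name, a position
in a two-level taxonomy (the default is a 13-category / 41-subcategory Greek
market scheme, shipped as data so other schemes can be loaded), free-text
`ingredient_text`, a list of free-text precautionary statements, and two
completeness flags. A product is analyzable only if its ingredient list was
readable *and* all package sides were imaged — precautionary statements have
no regulated position on the pack, so a partially imaged product cannot be
assessed for traces. A record failing both checks is counted once, under the
unreadable-list reason, mirroring a sequential exclusion protocol (readability
first, imaging second). `apply_exclusions()` is idempotent and partitions the
input exactly: every id lands in the retained set or the exclusion log, never
both, never neither.

A record claiming a readable ingredient list but carrying no ingredient text
is contradictory and rejected at validation time rather than silently treated
as empty.

## Allergen detection

All matching happens on normalized text (`normalize_text()`): lowercased,
accent- and diacritic-folded (both Latin and Greek; the Greek final sigma is
folded too), punctuation unified, whitespace collapsed. Lexicon terms pass
through the same normalization on load, so accented label text and unaccented
vocabulary meet on one canonical form.

`split_ingredient_list()` tokenizes an ingredient list on commas and
semicolons outside parentheses. Parenthetical sub-ingredients and
additive-function prefixes ("emulsifier: lecithins (soy)") stay inside their
parent phrase and are also exposed as child phrases, so a term hidden two
levels deep is still matchable. Percentages are stripped from the matchable
phrase but preserved as annotations. Unbalanced parentheses produce a warning
and a best-effort split, not an error — real labels are messy.

Detection is whole-word/phrase matching of a lexicon against those phrases.
The lexicon is data, not code: per allergen, canonical terms, derivative
terms (whey → milk, spelt → gluten cereals, named tree nuts → tree nuts),
E-number ranges (E220–E228 → sulphites), and exclusion patterns for claim
constructions. Two deliberate precedence rules:

* **Claims suppress only the claimed term.** "gluten-free oat flakes" removes
  the "gluten-free" span before matching, so "gluten" itself does not fire,
  but the oat derivative still maps to gluten cereals — a gluten-free claim
  on an oat product does not erase the regulatory status of oats. Suppressed
  claims are logged for audit.
* **Ingredient beats trace.** Statuses are ordered absent < trace <
  ingredient by potential exposure risk; an allergen declared both ways is
  counted once, as an ingredient. This keeps the bookkeeping identity
  `n_any = n_ingredient + n_trace` exact, so the any-scope, ingredient-scope,
  and trace-scope analyses never double count.

Precautionary statements are recognized by trigger phrases ("may contain
traces of", "manufactured in a facility that also processes", "may be
present", ...); all trigger variants map to the single trace status, since
adventitious presence and presence of traces are not distinguishable from
the label. A post-list "contains ..." statement is an *ingredient*
declaration, not a trace: it restates the list. A triggered statement naming
no known allergen yields a warning rather than a silent miss.

Only explicit terms count as matches. Implicit sources (a bare "flavouring"
that might carry milk) are not inferred — that would require information the
label does not provide. Fuzzy matching is deliberately absent: exact matching
on normalized text is reproducible and auditable, and the lexicon's
derivative lists are the intended mechanism for coverage.

## NOVA grading

`classify_nova()` is a four-branch cascade over the parsed phrases:

1. any ultra-processing marker (marker-class term or E-number in a marker
   range: sweeteners, flavourings, flavour enhancers, emulsifiers,
   thickeners, bulking agents, antioxidants, protein isolates/concentrates,
   added vitamins/minerals, hydrolyzed/extruded ingredients, extracts) →
   grade 4;
2. otherwise a single-ingredient product (water not counted) whose sole
   ingredient is culinary (salt, sugar, oil, starch, butter/animal fat,
   honey) → grade 2;
3. otherwise a multi-ingredient list containing a culinary term → grade 3;
4. otherwise grade 1 — including single non-culinary ingredients ("almonds").

A design point worth making explicit: a literal reading of marker lists that
include "added sodium" and "added oils" would send every salted or oiled
recipe to grade 4 and leave grade 3 empty, which contradicts how processed
foods (cheeses, canned vegetables, cured meats) are actually graded. The
default therefore routes plain culinary ingredients inside a recipe to grade
3, per the grade-3 definition (multiple ingredients, at least one of them a
culinary ingredient), and reserves grade 4 for industrial substances and
additive classes. The literal reading remains available as
`strict_nova4_markers = TRUE`.

Two further choices: an ingredient-count threshold ("five or more
ingredients") is recorded in the classification trace but never decides a
grade alone — counts are descriptive of ultra-processed foods, not
diagnostic; and subcategories that are industrially formulated by
construction (meat analogues, dairy imitations, prepared foods) can be
forced to grade 4 through a data-driven override table, which is **off** by
default so that default classification is purely text-based. Every
classification returns a trace (rule fired, matched markers, ingredient
count) sufficient to re-derive the grade without re-running.

## Statistics

For each subcategory, a NOVA-group × allergen-presence contingency table is
built (presence = at least one allergen in the chosen scope) and tested with
the Pearson chi-square statistic, no continuity correction, df = groups − 1.
The comparison is not applicable when a subcategory has a single NOVA group
or when prevalence is uniformly 100% or 0% (which also covers zero expected
cells); applicability is always judged on the any-scope table. Significance
defaults to α = 0.01 with no multiple-testing correction (a Bonferroni
option exists but is off by default, matching the reference analysis).

Rendering conventions follow the bundled reference survey table:
percentages at one decimal, round half up, with an exact 100 printed as
"100"; p-values rounded to three decimals first and printed "<0.01" only
when the rounded value falls below 0.005 — hence 0.0092 prints as "0.009",
not "<0.01".

Allergen-count summaries report, per grade and scope, the histogram of
counts and *both* mean conventions: the mean over all products and the mean
over declaring products. The reference survey's figures are internally
consistent only if the any/ingredient means are over all products and the
trace means over declaring products, so those are the reporting defaults —
but both are always computed and labelled, never silently chosen.

Diversity reporting collects the set of distinct allergens per
(subcategory, grade, scope) cell and compares NOVA4 against the pooled
NOVA1–3 comparator, flagging subcategories where the NOVA4 set is strictly
larger.

### The bundled reference table

`reference_survey_counts()` ships the published per-subcategory prevalence
summary of a Greek branded-food market survey (4587 analyzable products, 41
subcategories) verbatim, as validation data for the statistical layer.
Reconstructing its 13 testable contingency tables and re-running the engine
reproduces 12 of the 13 printed p-values to three decimals and exactly the
published count of 4 subcategories significant at α = 0.01. Two quirks of
the source are preserved and documented rather than corrected: the "Starchy
root or potato" row is internally inconsistent (its printed counts 13/18
imply 72.2%, not the printed 60.1%, and yield p = 0.093, not the printed
0.058), and the NOVA1 rows sum to 524 declaring products where the source's
own headline says 523 (58.0% = 523/901). The published headline aggregates
that cannot be derived from the table (3301/4587 overall, 3275 NOVA4, 2492
NOVA4-declaring) are shipped in `reference_survey_headlines()`.

```{r, eval = FALSE}
library(allergenova)
tabs <- reference_survey_tables()
pearson_chi_square(tabs[["Milk substitute"]])
#> Pearson chi-square: X2 = 1.8347, df = 2, p = 0.400
```

## The synthetic generator

`generate_labels()` emulates the *structure* of a branded-food database:
ground truth first (grade, ingredient-allergen set, trace-allergen set,
exclusion flags), text rendered afterwards to realize it. Grade-4 records
embed at least one marker phrase; grade-3 records a culinary term in a
multi-ingredient list; grade-2 records a single culinary ingredient, with
any ingredient-declared allergens rendered as a post-list "contains"
statement (so the single-ingredient property is preserved); grade-1 records
carry neither markers nor culinary terms. Allergens render as canonical or
derivative terms (probability `synonym_rate`), traces with weighted trigger
phrase variants. The rendering vocabulary is chosen so that no base food,
culinary term, or marker phrase collides with any allergen term — which is
what makes exact recovery a meaningful test.

Defaults are the reference survey's conditions: per-subcategory counts and
grade mixtures from the bundled table; per-grade allergen rates calibrated
once so that the probability of at least one allergen (14 independent
per-allergen draws at rate *r*, i.e. 1 − (1 − r)^14) matches the survey's
per-grade prevalences (ingredient scope: 41.7 / 47.8 / 67.5 / 70.8% for
NOVA1–4; trace scope: 28.7 / 1.4 / 10.2 / 45.4%); exclusion rates 27/4851
and 237/4851. Randomness is one seeded generator with per-record substreams
derived by hashing the product id, so a record's content never depends on
how many records precede it.

What the generator does **not** emulate: realistic marketing copy, brand
names, nutrient panels, market-share weighting, correlated allergen
co-occurrence (draws are independent per allergen), or out-of-vocabulary
spelling noise unless `out_of_lexicon_rate > 0` is set, in which case terms
are replaced by vocabulary deliberately absent from the lexicon and
detection/grading recall degrades by construction. Passing recovery tests on
synthetic data therefore demonstrates that the rules are implemented
faithfully and invertibly — not that the shipped English lexicon covers any
particular real market's labelling vocabulary.

## Numerical and degenerate-input choices

* Chi-square is delegated to `stats::chisq.test(correct = FALSE)` after the
  applicability rules; tests pin it against the closed-form 2×2 statistic
  n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)) at 1e-10.
* Empty ingredient list at classification time is an error (such records
  should have been excluded upstream); an empty *record set* everywhere else
  degrades to empty outputs, and a pipeline run retaining zero records
  writes an empty report with a warning.
* Zero-declaring groups report `mean_over_declaring` as NA, not 0.
* Ties in rounding go half up, because that is the convention the reference
  table itself uses ("58.0" from 523/901 = 58.05).

## Problem sizes

The shipped tests run the full pipeline on synthetic sets of roughly 450–700
records (10–15% of the reference survey's scale) — large enough that every
subcategory, grade, and scope is exercised and empirical rates converge,
while keeping the default suite fast; the type-I-error check uses 1000
simulated null tables. The generator handles the full 4587-record scale in
well under a minute where that is wanted.

## Known limitations

* Detection is lexicon-bound: a real market's derivative vocabulary is
  larger than any shipped list, and Greek coverage is a demonstration pack,
  not a curated national lexicon.
* NOVA grading from label text alone cannot see process information that is
  not declared (e.g. minimal processing of a multi-ingredient artisanal
  product), and no attempt is made to reproduce the grade of any specific
  commercial product.
* Allergen *quantity* and allergenicity are out of scope; presence of a
  declaration is the unit of analysis throughout.
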