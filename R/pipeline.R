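#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Exactly
#' one input source must be given: a records file (`records_path` +
#' `format`) or a synthetic generator configuration (`synthetic`).
#'
#' @param out_dir Output directory (created if missing).
#' @param records_path Optional path to a records CSV/JSON file.
#' @param format Input file format, `"csv"` or `"json"`.
#' @param synthetic Optional [synthetic_config()].
#' @param taxonomy_path,allergen_lexicon_path,marker_lexicon_path Optional
#'   paths overriding the bundled defaults.
#' @param alpha Significance level for the prevalence report.
#' @param strict_nova4_markers,overrides_enabled See [classify_nova()].
#' @param precaution_sep CSV dialect for multiple precautionary statements.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            records_path = NULL, format = "csv",
                            synthetic = NULL,
                            taxonomy_path = NULL,
                            allergen_lexicon_path = NULL,
                            marker_lexicon_path = NULL,
                            alpha = 0.01,
                            strict_nova4_markers = FALSE,
                            overrides_enabled = FALSE,
                            precaution_sep = "|") {
  if (is.null(records_path) == is.null(synthetic)) {
    stop("pipeline config error: give exactly one of records_path or synthetic",
         call. = FALSE)
  }
  if (!is.null(records_path) && !file.exists(records_path)) {
    stop("pipeline config error: records file not found: ", records_path,
         call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  structure(list(
    out_dir = out_dir, records_path = records_path, format = format,
    synthetic = synthetic, taxonomy_path = taxonomy_path,
    allergen_lexicon_path = allergen_lexicon_path,
    marker_lexicon_path = marker_lexicon_path, alpha = alpha,
    strict_nova4_markers = strict_nova4_markers,
    overrides_enabled = overrides_enabled, precaution_sep = precaution_sep),
    class = "pipeline_config")
}

flatten_diversity <- function(div_cells) {
  div_cells |>
    dplyr::mutate(allergens = vapply(.data$allergens, paste, character(1),
                                     collapse = "|")) |>
    dplyr::arrange(.data$subcategory, .data$group)
}

#' Run the full label-analysis pipeline
#'
#' read -> exclude -> detect allergens -> classify NOVA -> analyze ->
#' export. Writes, under `config$out_dir`: `exclusion_log.json`,
#' `excluded.csv`, `profiles_grades.csv` (per retained record),
#' `prevalence_report.csv`, `counts_summary.csv` and
#' `counts_histogram_<scope>.csv` for the three scopes,
#' `diversity_<scope>.csv` + `diversity_comparison.csv`, `headlines.json`,
#' and a `manifest.json` (configuration echo, input/lexicon checksums,
#' package version) that fully determines the outputs: equal manifests
#' imply byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results (`records`,
#'   `exclusions`, `profiles`, `grades`, `analysis`, `report`, `headlines`,
#'   `paths`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  taxonomy <- if (is.null(config$taxonomy_path)) default_taxonomy() else
    load_taxonomy(config$taxonomy_path)
  lexicon <- load_allergen_lexicon(config$allergen_lexicon_path)
  markers <- load_marker_lexicon(config$marker_lexicon_path)

  if (!is.null(config$records_path)) {
    say("read", "reading ", config$records_path)
    records <- read_records(config$records_path, config$format, taxonomy,
                            config$precaution_sep)
  } else {
    say("read", "generating synthetic records (seed ", config$synthetic$seed, ")")
    records <- generate_labels(config$synthetic, taxonomy)$records
  }

  excl <- apply_exclusions(records)
  say("exclude", excl$log$n_input, " in, ", excl$log$n_retained, " retained")
  jsonlite::write_json(unclass(excl$log)[c("n_input", "n_unreadable_excluded",
                                           "n_incomplete_package_excluded",
                                           "n_retained")],
                       p("exclusion_log.json"), auto_unbox = TRUE, pretty = TRUE)
  readr::write_csv(excl$log$excluded, p("excluded.csv"), progress = FALSE)

  if (!nrow(excl$retained)) {
    warning("no records retained; writing empty report", call. = FALSE)
    readr::write_csv(tibble::tibble(product_id = character()),
                     p("profiles_grades.csv"), progress = FALSE)
    headlines <- list(n_products = 0L)
    jsonlite::write_json(headlines, p("headlines.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    write_manifest(config, p("manifest.json"), lexicon, markers)
    return(invisible(list(records = records, exclusions = excl$log,
                          headlines = headlines,
                          paths = list.files(config$out_dir, full.names = TRUE))))
  }

  say("detect", "building allergen profiles for ", nrow(excl$retained),
      " records")
  profiles <- build_profiles(excl$retained, lexicon)
  say("classify", "assigning NOVA grades")
  grades <- classify_all(excl$retained, markers,
                         config$strict_nova4_markers, config$overrides_enabled)
  analysis <- assemble_analysis(excl$retained, profiles, grades)

  per_record <- analysis |>
    dplyr::left_join(grades[c("product_id", "rule_fired", "n_ingredients")],
                     by = "product_id")
  readr::write_csv(per_record, p("profiles_grades.csv"), progress = FALSE)

  say("analyze", "prevalence report (alpha = ", config$alpha, ")")
  report <- prevalence_report(analysis, alpha = config$alpha)
  readr::write_csv(report, p("prevalence_report.csv"), progress = FALSE)

  for (scope in c("any", "ingredient", "trace")) {
    cs <- count_summary(analysis, scope)
    hist <- cs |>
      dplyr::select("nova", "histogram") |>
      tidyr::unnest("histogram")
    readr::write_csv(hist, p(sprintf("counts_histogram_%s.csv", scope)),
                     progress = FALSE)
    cs$histogram <- NULL
    cs$scope <- scope
    readr::write_csv(cs, p(sprintf("counts_summary_%s.csv", scope)),
                     progress = FALSE)
    div <- diversity_report(profiles, analysis, scope)
    readr::write_csv(flatten_diversity(div$cells),
                     p(sprintf("diversity_%s.csv", scope)), progress = FALSE)
    if (scope == "any") {
      readr::write_csv(div$comparison, p("diversity_comparison.csv"),
                       progress = FALSE)
    }
  }

  headlines <- summarize_headlines(analysis, alpha = config$alpha)
  jsonlite::write_json(headlines, p("headlines.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_manifest(config, p("manifest.json"), lexicon, markers)
  say("done", "artifacts in ", config$out_dir)
  invisible(list(records = records, exclusions = excl$log,
                 profiles = profiles, grades = grades, analysis = analysis,
                 report = report, headlines = headlines,
                 paths = list.files(config$out_dir, full.names = TRUE)))
}

write_manifest <- function(config, path, lexicon, markers) {
  cfg <- unclass(config)
  # identify inputs by name + checksum, not by machine-local paths, so that
  # equal analyses produce equal manifests wherever they run
  cfg$out_dir <- NULL
  cfg$records_path <- if (!is.null(cfg$records_path)) basename(cfg$records_path)
  cfg$taxonomy_path <- if (!is.null(cfg$taxonomy_path)) basename(cfg$taxonomy_path)
  cfg$allergen_lexicon_path <- NULL
  cfg$marker_lexicon_path <- NULL
  cfg$synthetic <- if (!is.null(cfg$synthetic)) {
    s <- unclass(cfg$synthetic)
    s$grade_mixture <- NULL # bulky; determined by seed + reference defaults
    s$ingredient_rates <- as.vector(s$ingredient_rates)
    s$trace_rates <- as.vector(s$trace_rates)
    s
  }
  manifest <- list(
    package = "allergenova",
    version = as.character(utils::packageVersion("allergenova")),
    config = cfg,
    allergen_lexicon = list(name = lexicon$name, version = lexicon$version,
                            md5 = unname(tools::md5sum(lexicon$path))),
    marker_lexicon = list(name = markers$name, version = markers$version,
                          md5 = unname(tools::md5sum(markers$path))),
    records_md5 = if (!is.null(config$records_path))
      unname(tools::md5sum(config$records_path)) else NULL)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Headline summary of an analysis
#'
#' The market-level comparators: overall allergen prevalence, the
#' ultra-processed (NOVA4) share, per-grade prevalence by scope, per-grade
#' mean allergen counts (mean over all products for the any/ingredient
#' scopes, mean over declaring products for the trace scope), and the
#' number of subcategories whose NOVA groups differ significantly.
#'
#' @param analysis Output of [assemble_analysis()].
#' @param alpha Significance level.
#' @return A list: `n_products`, `overall_prevalence_pct`, `upf_share_pct`,
#'   `per_grade` (tibble), `n_testable_subcategories`,
#'   `n_significant_subcategories`, `alpha`.
#' @export
summarize_headlines <- function(analysis, alpha = 0.01) {
  report <- prevalence_report(analysis, alpha = alpha)
  per_grade <- dplyr::bind_rows(lapply(c("any", "ingredient", "trace"),
    function(scope) {
      cs <- count_summary(analysis, scope)
      cs$histogram <- NULL
      cs$scope <- scope
      cs$mean_reported <- if (scope == "trace") cs$mean_over_declaring else
        cs$mean_over_all
      cs
    }))
  list(
    n_products = nrow(analysis),
    overall_prevalence_pct = headline_pct(sum(analysis$n_any >= 1L),
                                          nrow(analysis)),
    upf_share_pct = headline_pct(sum(analysis$nova == 4L), nrow(analysis)),
    per_grade = per_grade,
    n_testable_subcategories = attr(report, "n_testable"),
    n_significant_subcategories = attr(report, "n_significant"),
    alpha = alpha)
}
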