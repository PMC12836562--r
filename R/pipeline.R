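#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Run the full multimodal phenotyping pipeline
#'
#' Orchestrates the stages end to end: build the HNC cohort, extract rare
#' evidence from the three sources within it, assemble cohort assignments
#' and source attribution, and — when gold annotations are supplied —
#' evaluate every cohort and single source.  Optionally writes all
#' artifacts (`cohort.csv`, `evidence.csv`, `attribution.json`,
#' `metrics.json`, `summary.csv`, `manifest.json`) to a directory.
#'
#' @param dataset An `ehr_dataset`, or an `ehr_simulation` (its dataset and
#'   gold are used).
#' @param gold Optional gold-label tibble; taken from the simulation when
#'   `dataset` is an `ehr_simulation`.
#' @param out_dir Optional output directory.
#' @param codesets,dictionary,lexicon,triggers Engine configurations
#'   (shipped defaults when `NULL`-omitted).
#' @param rounding Metric rounding mode, `"raw"` or `"paper"`.
#' @param concordance_within_flavour Passed to [build_assignments()].
#' @param verbose Print the cohort funnel as the stages run.
#' @return An object of class `rarehnc_pipeline`: list with `cohort`,
#'   `evidence`, `assignments`, `attribution`, `summary`, and (with gold)
#'   `evaluation`.
#' @export
run_pipeline <- function(dataset, gold = NULL, out_dir = NULL,
                         codesets = default_codesets(),
                         dictionary = default_adicap_dictionary(),
                         lexicon = default_lexicon(),
                         triggers = default_triggers(),
                         rounding = c("raw", "paper"),
                         concordance_within_flavour = FALSE,
                         verbose = FALSE) {
  rounding <- match.arg(rounding)
  if (inherits(dataset, "ehr_simulation")) {
    gold <- gold %||% dataset$gold
    dataset <- dataset$dataset
  }
  say <- function(...) if (verbose) inform(sprintf(...))
  say("persons: %d", nrow(dataset$persons))

  cohort <- build_hnc_cohort(dataset, codesets, dictionary)
  say("HNC cohort (HNC code + pathology report): %d", nrow(cohort))

  evidence <- collect_evidence(dataset, cohort, codesets, dictionary,
                               lexicon, triggers)
  assignments <- build_assignments(dataset, evidence, cohort,
                                   concordance_within_flavour)
  say("rare: %d (topography %d, histology %d); consolidated: %d",
      sum(assignments$in_rare), sum(assignments$in_rare_topography),
      sum(assignments$in_rare_histology), sum(assignments$in_consolidated))

  attribution <- source_attribution(assignments)
  summary <- cohort_summary(assignments, dataset$persons)
  evaluation <- if (!is.null(gold)) {
    evaluate_cohorts(assignments, evidence, gold, rounding = rounding)
  }

  out <- structure(
    list(cohort = cohort, evidence = evidence, assignments = assignments,
         attribution = attribution, summary = summary,
         evaluation = evaluation),
    class = "rarehnc_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$assignments, file.path(out_dir, "cohort.csv"))
  readr::write_csv(result$evidence, file.path(out_dir, "evidence.csv"),
                   progress = FALSE)
  readr::write_csv(result$summary, file.path(out_dir, "summary.csv"),
                   progress = FALSE)
  jsonlite::write_json(result$attribution,
                       file.path(out_dir, "attribution.json"),
                       auto_unbox = FALSE, digits = NA)
  if (!is.null(result$evaluation)) {
    jsonlite::write_json(as_tibble(result$evaluation),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = FALSE, digits = NA, na = "null")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("rarehnc")),
    n_cohort = nrow(result$cohort),
    n_rare = sum(result$assignments$in_rare),
    n_consolidated = sum(result$assignments$in_consolidated),
    content_hash = rlang::hash(list(result$assignments, result$evidence))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.rarehnc_pipeline <- function(x, ...) {
  cat("<rarehnc_pipeline>\n")
  cat(sprintf("  HNC cohort:    %d\n", nrow(x$cohort)))
  cat(sprintf("  rare:          %d (topography %d, histology %d)\n",
              sum(x$assignments$in_rare),
              sum(x$assignments$in_rare_topography),
              sum(x$assignments$in_rare_histology)))
  cat(sprintf("  consolidated:  %d\n", sum(x$assignments$in_consolidated)))
  if (!is.null(x$evaluation)) {
    cat("  evaluation:\n")
    print(as_tibble(x$evaluation)[, c("row", "tp", "fp", "fn", "tn",
                                      "sensitivity", "specificity", "ppv",
                                      "npv")])
  }
  invisible(x)
}
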