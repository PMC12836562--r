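#' Confusion matrix of a predicted patient set against gold labels
#'
#' Tallies TP/FP/FN/TN of a predicted patient set over an annotated
#' universe.  The gold table must cover every universe member; the predicted
#' set must be a subset of the universe.
#'
#' @param predicted Character vector (or one-column data frame) of predicted
#'   positive `person_id`s.
#' @param gold Gold-label tibble (see [read_gold()]).
#' @param universe Character vector of annotated `person_id`s.
#' @param label Gold column to evaluate against (default `"is_rare_hnc"`).
#' @return One-row tibble with integer columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(predicted, gold, universe,
                             label = "is_rare_hnc") {
  if (is.data.frame(predicted)) predicted <- predicted$person_id
  predicted <- unique(as_chr(predicted))
  universe <- unique(as_chr(universe))
  extra <- setdiff(predicted, universe)
  if (length(extra) > 0) {
    abort(sprintf("predicted patients outside the annotated universe: %s",
                  paste(utils::head(extra, 5), collapse = ", ")),
          class = "rarehnc_evaluation_error")
  }
  missing <- setdiff(universe, gold$person_id)
  if (length(missing) > 0) {
    abort(sprintf("gold annotation missing for universe member(s): %s",
                  paste(utils::head(missing, 5), collapse = ", ")),
          class = "rarehnc_evaluation_error")
  }
  pos <- gold$person_id[gold[[label]]]
  pos <- intersect(universe, pos)
  neg <- setdiff(universe, pos)
  tibble(
    tp = length(intersect(predicted, pos)),
    fp = length(intersect(predicted, neg)),
    fn = length(setdiff(pos, predicted)),
    tn = length(setdiff(neg, predicted))
  )
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' Computes sensitivity, specificity, PPV and NPV on the percent scale.
#' `rounding = "raw"` (the default) keeps full precision for programmatic
#' use; `rounding = "paper"` rounds half-to-even to whole percentages, the
#' convention used in published validation tables (62.5 prints as 62).
#' A zero denominator yields `NA` (undefined), never an error, and
#' serializes as `null`.
#'
#' @param cm Data frame with columns `tp`, `fp`, `fn`, `tn` (one or more
#'   rows; extra columns pass through).
#' @param rounding `"raw"` or `"paper"`.
#' @return `cm` with added numeric columns `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @examples
#' dx_metrics(data.frame(tp = 20, fp = 4, fn = 2, tn = 74), "paper")
#' @export
dx_metrics <- function(cm, rounding = c("raw", "paper")) {
  rounding <- match.arg(rounding)
  cm <- as_tibble(cm)
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(cm)))
  if (any(cm$tp < 0 | cm$fp < 0 | cm$fn < 0 | cm$tn < 0)) {
    abort("confusion counts must be non-negative",
          class = "rarehnc_evaluation_error")
  }
  pct <- function(num, den) ifelse(den == 0, NA_real_, 100 * num / den)
  out <- cm %>%
    mutate(
      sensitivity = pct(.data$tp, .data$tp + .data$fn),
      specificity = pct(.data$tn, .data$tn + .data$fp),
      ppv = pct(.data$tp, .data$tp + .data$fp),
      npv = pct(.data$tn, .data$tn + .data$fn)
    )
  if (rounding == "paper") {
    out <- out %>%
      mutate(across(c("sensitivity", "specificity", "ppv", "npv"),
                    ~ round(.x)))
  }
  out
}

#' Both conventions of the NLP false-positive rate
#'
#' Validation write-ups sometimes report the false-positive count over the
#' whole annotated set (FP/total) and sometimes the complement of
#' specificity (FP/(FP+TN)).  Both are returned, clearly labelled.
#'
#' @param cm Data frame with columns `tp`, `fp`, `fn`, `tn`.
#' @return Tibble with `fp_per_total` and `fp_per_negative`, percent scale.
#' @export
false_positive_rates <- function(cm) {
  cm <- as_tibble(cm)
  tot <- cm$tp + cm$fp + cm$fn + cm$tn
  tibble(
    fp_per_total = ifelse(tot == 0, NA_real_, 100 * cm$fp / tot),
    fp_per_negative = ifelse(cm$fp + cm$tn == 0, NA_real_,
                             100 * cm$fp / (cm$fp + cm$tn))
  )
}

#' Published validation confusion matrices
#'
#' The seven confusion matrices from the chart-review validation of the
#' multimodal rare-HNC algorithm on 100 annotated HNC patients: one row per
#' single data source (ICD-10, ADICAP, NLP free text) and one per cohort
#' (rare, rare-topography and rare-histology subcohorts, consolidated).
#' Feeding them to [dx_metrics()] in `"paper"` mode reproduces all 28
#' published Se/Sp/PPV/NPV percentages.
#'
#' @return Tibble with `row`, `label`, `tp`, `fp`, `fn`, `tn`.
#' @export
validation_matrices <- function() {
  tibble(
    row = c("icd10", "adicap", "nlp",
            "rare", "rare_topography", "rare_histology", "consolidated"),
    label = c("ICD-10 code", "ADICAP code", "NLP-processed free text",
              "Rare HNC patient cohort",
              "Rare topography HNC patient subcohort",
              "Rare histology HNC patient subcohort",
              "Consolidated rare HNC patient cohort"),
    tp = c(15L, 14L, 21L, 22L, 18L, 16L, 20L),
    fp = c(9L, 3L, 9L, 25L, 24L, 5L, 4L),
    fn = c(7L, 8L, 1L, 0L, 0L, 2L, 2L),
    tn = c(69L, 75L, 69L, 53L, 58L, 77L, 74L)
  )
}

#' @rdname validation_matrices
#' @param rounding Passed to [dx_metrics()]; `"paper"` reproduces the
#'   published whole-percent values.
#' @export
reproduce_validation_tables <- function(rounding = "paper") {
  dx_metrics(validation_matrices(), rounding)
}

#' Evaluate all cohorts and single sources against gold annotations
#'
#' Builds one confusion matrix + metric set per evaluation row: the three
#' single-source predictions (patients with any rare evidence from ICD-10,
#' ADICAP or NLP respectively, each judged against the overall rare-HNC gold
#' flag) and the four cohorts (rare cohort and consolidated cohort against
#' the rare-HNC flag; the topography and histology subcohorts against their
#' flavour-specific gold flags).
#'
#' @param assignments Assignment tibble from [build_assignments()].
#' @param evidence Evidence tibble from [collect_evidence()].
#' @param gold Gold-label tibble (see [read_gold()]).
#' @param universe Annotated universe of `person_id`s; defaults to the
#'   patients in `assignments` (the HNC cohort).
#' @param rounding Passed to [dx_metrics()].
#' @return An object of class `hnc_evaluation`: a tibble with `row`,
#'   `gold_label`, the confusion counts and the four metrics.
#' @export
evaluate_cohorts <- function(assignments, evidence, gold, universe = NULL,
                             rounding = c("raw", "paper")) {
  rounding <- match.arg(rounding)
  universe <- universe %||% assignments$person_id
  universe <- unique(as_chr(universe))
  evidence <- evidence %>% filter(.data$person_id %in% universe)
  assignments <- assignments %>% filter(.data$person_id %in% universe)

  source_pred <- function(src) {
    unique(evidence$person_id[evidence$source == src])
  }
  rows <- list(
    icd10 = list(pred = source_pred("ICD10"), label = "is_rare_hnc"),
    adicap = list(pred = source_pred("ADICAP"), label = "is_rare_hnc"),
    nlp = list(pred = source_pred("NLP"), label = "is_rare_hnc"),
    rare = list(pred = assignments$person_id[assignments$in_rare],
                label = "is_rare_hnc"),
    rare_topography = list(
      pred = assignments$person_id[assignments$in_rare_topography],
      label = "is_rare_topography"),
    rare_histology = list(
      pred = assignments$person_id[assignments$in_rare_histology],
      label = "is_rare_histology"),
    consolidated = list(
      pred = assignments$person_id[assignments$in_consolidated],
      label = "is_rare_hnc")
  )
  out <- purrr::imap_dfr(rows, function(r, nm) {
    confusion_matrix(r$pred, gold, universe, r$label) %>%
      mutate(row = nm, gold_label = r$label, .before = 1)
  })
  out <- dx_metrics(out, rounding)
  structure(out, class = c("hnc_evaluation", class(out)),
            universe_size = length(universe), rounding = rounding)
}

#' @export
print.hnc_evaluation <- function(x, ...) {
  cat(sprintf("<hnc_evaluation> %d annotated patients, rounding = %s\n",
              attr(x, "universe_size"), attr(x, "rounding")))
  NextMethod()
}

#' Tidy an evaluation into one row per metric
#'
#' @param x An `hnc_evaluation` from [evaluate_cohorts()].
#' @param ... Unused.
#' @return Long tibble with `row`, `metric`, `value`.
#' @exportS3Method generics::tidy
tidy.hnc_evaluation <- function(x, ...) {
  as_tibble(x) %>%
    select("row", "sensitivity", "specificity", "ppv", "npv") %>%
    tidyr::pivot_longer(-"row", names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation
#'
#' @param x An `hnc_evaluation` from [evaluate_cohorts()].
#' @param ... Unused.
#' @return One-row tibble: universe size, gold rare prevalence, and the
#'   consolidated cohort's four metrics.
#' @exportS3Method generics::glance
glance.hnc_evaluation <- function(x, ...) {
  cons <- as_tibble(x) %>% filter(.data$row == "consolidated")
  tibble(
    n_annotated = attr(x, "universe_size"),
    prevalence_rare = 100 * (cons$tp + cons$fn) / attr(x, "universe_size"),
    consolidated_sensitivity = cons$sensitivity,
    consolidated_specificity = cons$specificity,
    consolidated_ppv = cons$ppv,
    consolidated_npv = cons$npv
  )
}

#' Plot evaluation metrics by row
#'
#' @param object An `hnc_evaluation` from [evaluate_cohorts()].
#' @param ... Unused.
#' @return A ggplot: grouped bars of Se/Sp/PPV/NPV per evaluation row.
#' @exportS3Method ggplot2::autoplot
autoplot.hnc_evaluation <- function(object, ...) {
  dat <- tidy(object) %>%
    mutate(row = factor(.data$row, levels = unique(.data$row)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$row, y = .data$value,
                                    fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the source-attribution partition
#'
#' @param attribution Tibble from [source_attribution()].
#' @return A ggplot: patient counts per source combination, one panel per
#'   cohort.
#' @export
plot_source_attribution <- function(attribution) {
  ggplot2::ggplot(attribution,
                  ggplot2::aes(x = .data$sources, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~cohort, scales = "free_x") +
    ggplot2::labs(x = "identifying source combination", y = "patients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Descriptive summary of a cohort
#'
#' Median age with interquartile range (computed against a reference year)
#' and the male:female sex ratio, with missing demographics reported as
#' counts rather than silently dropped.
#'
#' @param assignments Assignment tibble from [build_assignments()].
#' @param persons Persons tibble (`person_id`, `birth_year`, `sex`).
#' @param reference_year Year against which ages are computed.
#' @return One-row tibble per cohort flag: `cohort`, `n`, `median_age`,
#'   `age_q1`, `age_q3`, `n_age_missing`, `n_male`, `n_female`,
#'   `n_sex_unknown`, `sex_ratio` (`NA` when undefined).
#' @export
cohort_summary <- function(assignments, persons, reference_year = 2024) {
  cohorts <- list(
    hnc = assignments$person_id[assignments$in_hnc],
    rare = assignments$person_id[assignments$in_rare],
    rare_topography = assignments$person_id[assignments$in_rare_topography],
    rare_histology = assignments$person_id[assignments$in_rare_histology],
    consolidated = assignments$person_id[assignments$in_consolidated]
  )
  purrr::imap_dfr(cohorts, function(ids, nm) {
    p <- persons %>% filter(.data$person_id %in% ids)
    ages <- reference_year - p$birth_year
    known <- ages[!is.na(ages)]
    q <- if (length(known) > 0) stats::quantile(known, c(0.25, 0.5, 0.75),
                                                type = 7, names = FALSE)
         else rep(NA_real_, 3)
    n_m <- sum(p$sex == "male", na.rm = TRUE)
    n_f <- sum(p$sex == "female", na.rm = TRUE)
    tibble(
      cohort = nm, n = length(ids),
      median_age = q[2], age_q1 = q[1], age_q3 = q[3],
      n_age_missing = sum(is.na(ages)),
      n_male = n_m, n_female = n_f,
      n_sex_unknown = sum(is.na(p$sex) | p$sex == "unknown"),
      sex_ratio = if (n_f > 0) n_m / n_f else NA_real_
    )
  })
}
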