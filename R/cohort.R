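#' Build the HNC patient cohort
#'
#' A patient belongs to the head-and-neck-cancer cohort when they have an
#' HNC signal from structured data — an HNC ICD-10 code in an admissible
#' cohort position (default primary/related) or a malignant HNC ADICAP code —
#' AND at least one pathology report available.  Patients with HNC codes but
#' no pathology report are excluded: downstream extraction works on
#' pathology reports.
#'
#' @param dataset An `ehr_dataset`.
#' @param codesets ICD-10 code-set configuration; see [read_codesets()].
#' @param dictionary ADICAP dictionary; see [read_adicap_dictionary()].
#' @return Tibble with one column `person_id` (the cohort members).
#' @export
build_hnc_cohort <- function(dataset, codesets = default_codesets(),
                             dictionary = default_adicap_dictionary()) {
  icd <- icd10_hnc_flags(dataset$claims, codesets)
  adi <- adicap_hnc_flags(dataset$notes, dictionary)
  has_report <- dataset$notes %>%
    filter(.data$note_type == "pathology_report") %>%
    distinct(.data$person_id)
  flagged <- union(icd$person_id[icd$icd10_hnc], adi$person_id[adi$adicap_hnc])
  tibble(person_id = intersect(flagged, has_report$person_id)) %>%
    arrange(.data$person_id)
}

#' Collect rare-HNC evidence from all three sources
#'
#' Runs the ICD-10, ADICAP and NLP engines over a dataset and stacks their
#' patient-level evidence rows.  When `cohort` is supplied, claims and notes
#' are first restricted to cohort members, mirroring the design in which
#' rare-variable extraction happens within the HNC cohort.
#'
#' @param dataset An `ehr_dataset`.
#' @param cohort Optional tibble/vector of cohort `person_id`s.
#' @param codesets,dictionary,lexicon,triggers Engine configurations.
#' @param require_malignant_for_topo Passed to [adicap_evidence()].
#' @param histology_requires_hnc_context Passed to [nlp_evidence()].
#' @return Evidence tibble: `person_id`, `source` in
#'   `{"ICD10","ADICAP","NLP"}`, `flavour` in
#'   `{"rare_topography","rare_histology"}`, `provenance`.
#' @export
collect_evidence <- function(dataset, cohort = NULL,
                             codesets = default_codesets(),
                             dictionary = default_adicap_dictionary(),
                             lexicon = default_lexicon(),
                             triggers = default_triggers(),
                             require_malignant_for_topo = TRUE,
                             histology_requires_hnc_context = FALSE) {
  claims <- dataset$claims
  notes <- dataset$notes
  if (!is.null(cohort)) {
    ids <- if (is.data.frame(cohort)) cohort$person_id else as_chr(cohort)
    claims <- claims %>% filter(.data$person_id %in% ids)
    notes <- notes %>% filter(.data$person_id %in% ids)
  }
  bind_rows(
    icd10_evidence(claims, codesets),
    adicap_evidence(notes, dictionary, require_malignant_for_topo),
    nlp_evidence(notes, lexicon, triggers, histology_requires_hnc_context)
  ) %>% arrange(.data$person_id, .data$source, .data$flavour)
}

#' Build per-patient cohort assignments
#'
#' Combines the HNC cohort with the pooled evidence into one row per cohort
#' patient with the five membership flags:
#' * `in_rare_topography` — any rare-topography evidence (ICD-10, ADICAP or
#'   NLP);
#' * `in_rare_histology` — any rare-histology evidence (ADICAP or NLP;
#'   ICD-10 cannot assert histology);
#' * `in_rare` — their union;
#' * `in_consolidated` — rare with evidence from at least two distinct
#'   sources.  By default sources are counted at patient level across
#'   flavours; set `concordance_within_flavour = TRUE` to require the two
#'   sources to agree on the same rarity flavour.
#'
#' Evidence attached to patients outside the HNC cohort is dropped with a
#' warning, never silently kept.
#'
#' @param dataset An `ehr_dataset`.
#' @param evidence Evidence tibble from [collect_evidence()].
#' @param cohort Optional precomputed HNC cohort (tibble with `person_id`);
#'   computed from `dataset` when `NULL`.
#' @param concordance_within_flavour Count sources within each flavour
#'   separately when testing the two-source consolidation rule.
#' @param codesets,dictionary Used only when `cohort` is `NULL`.
#' @return Assignment tibble: `person_id`, `in_hnc`, `in_rare_topography`,
#'   `in_rare_histology`, `in_rare`, `in_consolidated`, and `sources` (a
#'   list-column of distinct contributing source tags; empty for patients
#'   with no rare evidence).
#' @export
build_assignments <- function(dataset, evidence, cohort = NULL,
                              concordance_within_flavour = FALSE,
                              codesets = default_codesets(),
                              dictionary = default_adicap_dictionary()) {
  if (is.null(cohort)) {
    cohort <- build_hnc_cohort(dataset, codesets, dictionary)
  }
  ids <- if (is.data.frame(cohort)) cohort$person_id else as_chr(cohort)
  bad <- evidence %>% filter(!.data$person_id %in% ids)
  if (nrow(bad) > 0) {
    warn(sprintf(
      "dropping %d evidence row(s) for %d patient(s) outside the HNC cohort: %s",
      nrow(bad), length(unique(bad$person_id)),
      paste(utils::head(unique(bad$person_id), 5), collapse = ", ")
    ), class = "rarehnc_evidence_dropped")
    evidence <- evidence %>% filter(.data$person_id %in% ids)
  }
  if (any(evidence$source == "ICD10" & evidence$flavour == "rare_histology")) {
    abort("invalid evidence: ICD10 cannot carry rare_histology",
          class = "rarehnc_integrity_error")
  }

  per_patient <- evidence %>%
    group_by(.data$person_id) %>%
    summarise(
      in_rare_topography = any(.data$flavour == "rare_topography"),
      in_rare_histology = any(.data$flavour == "rare_histology"),
      sources = list(sort(unique(.data$source))),
      n_sources = if (concordance_within_flavour) {
        max(length(unique(.data$source[.data$flavour == "rare_topography"])),
            length(unique(.data$source[.data$flavour == "rare_histology"])))
      } else {
        length(unique(.data$source))
      },
      .groups = "drop"
    )

  tibble(person_id = ids) %>%
    left_join(per_patient, by = "person_id") %>%
    mutate(
      in_hnc = TRUE,
      in_rare_topography = coalesce(.data$in_rare_topography, FALSE),
      in_rare_histology = coalesce(.data$in_rare_histology, FALSE),
      in_rare = .data$in_rare_topography | .data$in_rare_histology,
      n_sources = coalesce(.data$n_sources, 0L),
      in_consolidated = .data$in_rare & .data$n_sources >= 2L,
      sources = purrr::map(.data$sources, ~ .x %||% character())
    ) %>%
    select("person_id", "in_hnc", "in_rare_topography", "in_rare_histology",
           "in_rare", "in_consolidated", "sources") %>%
    arrange(.data$person_id)
}

#' Source attribution of cohort members
#'
#' Counts patients per non-empty combination of contributing sources within
#' each of the rare cohorts — the tabular equivalent of a Venn diagram of
#' ICD-10 / ADICAP / NLP identification.
#'
#' @param assignments Assignment tibble from [build_assignments()].
#' @return Tibble with `cohort` (`rare`, `rare_topography`,
#'   `rare_histology`, `consolidated`), `sources` (rendered token, e.g.
#'   `"ADICAP+NLP"`) and `n`.  Within each cohort the counts sum to the
#'   cohort size.
#' @export
source_attribution <- function(assignments) {
  one <- function(members, name) {
    if (nrow(members) == 0) {
      return(tibble(cohort = character(), sources = character(),
                    n = integer()))
    }
    members %>%
      mutate(sources = render_sources(.data$sources)) %>%
      count(.data$sources, name = "n") %>%
      mutate(cohort = name) %>%
      select("cohort", "sources", "n")
  }
  bind_rows(
    one(assignments %>% filter(.data$in_rare), "rare"),
    one(assignments %>% filter(.data$in_rare_topography), "rare_topography"),
    one(assignments %>% filter(.data$in_rare_histology), "rare_histology"),
    one(assignments %>% filter(.data$in_consolidated), "consolidated")
  )
}
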