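test_that("HNC cohort requires an HNC code AND a pathology report", {
  ds <- bind_cases(
    patient_case("P1"),                        # HNC claim + report
    patient_case("P2", has_report = FALSE),    # HNC claim, no report
    list(persons = tibble::tibble(person_id = "P3"),  # MDM note only
         claims = tibble::tibble(person_id = "P3", icd10_code = "C09",
                                 diagnosis_position = "primary"),
         notes = tibble::tibble(note_id = "P3-m", person_id = "P3",
                                note_type = "mdm_report", text = "RCP.")),
    list(persons = tibble::tibble(person_id = "P4"),  # report, non-HNC claim
         claims = tibble::tibble(person_id = "P4", icd10_code = "C50",
                                 diagnosis_position = "primary"),
         notes = tibble::tibble(note_id = "P4-n", person_id = "P4",
                                note_type = "pathology_report",
                                text = "Prolifération maligne.\nCode ADICAP : BHSN7081"))
  )
  expect_equal(build_hnc_cohort(ds)$person_id, "P1")
})

test_that("an ADICAP HNC code admits a patient without any HNC claim", {
  ds <- list(
    persons = tibble::tibble(person_id = "P1"),
    claims = tibble::tibble(person_id = "P1", icd10_code = "C50",
                            diagnosis_position = "primary"),
    notes = tibble::tibble(note_id = "N1", person_id = "P1",
                           note_type = "pathology_report",
                           text = "Code ADICAP : BHLA7080")
  )
  ds <- ehr_dataset(ds$persons, ds$claims, ds$notes)
  expect_equal(build_hnc_cohort(ds)$person_id, "P1")
})

# 8-case truth table over {ICD-10 rare claim, ADICAP rare code, NLP asserted
# rare mention} x report availability, memberships derived by hand from the
# cohort definitions before implementation:
#   in_rare      <=> any source evidence (and in the HNC cohort)
#   consolidated <=> >= 2 distinct sources
#   no report    => not even in the HNC cohort, whatever the claims say
truth_table <- tibble::tribble(
  ~id,   ~icd, ~adi, ~nlp, ~report, ~in_hnc, ~in_rare, ~in_cons,
  "T000", FALSE, FALSE, FALSE, TRUE,  TRUE,  FALSE, FALSE,
  "T100", TRUE,  FALSE, FALSE, TRUE,  TRUE,  TRUE,  FALSE,
  "T010", FALSE, TRUE,  FALSE, TRUE,  TRUE,  TRUE,  FALSE,
  "T001", FALSE, FALSE, TRUE,  TRUE,  TRUE,  TRUE,  FALSE,
  "T110", TRUE,  TRUE,  FALSE, TRUE,  TRUE,  TRUE,  TRUE,
  "T101", TRUE,  FALSE, TRUE,  TRUE,  TRUE,  TRUE,  TRUE,
  "T011", FALSE, TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,
  "T111", TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE
)

build_truth_dataset <- function() {
  cases <- purrr::pmap(truth_table, function(id, icd, adi, nlp, report, ...) {
    patient_case(id, icd10_rare_claim = icd, adicap_rare = adi,
                 nlp_rare = nlp, has_report = report)
  })
  do.call(bind_cases, cases)
}

test_that("the 8-case truth table yields exactly the mandated memberships", {
  ds <- build_truth_dataset()
  cohort <- build_hnc_cohort(ds)
  expect_setequal(cohort$person_id,
                  truth_table$id[truth_table$in_hnc])
  ev <- collect_evidence(ds, cohort)
  asg <- build_assignments(ds, ev, cohort)
  got <- asg[match(truth_table$id[truth_table$in_hnc], asg$person_id), ]
  want <- truth_table[truth_table$in_hnc, ]
  expect_equal(got$in_rare, want$in_rare)
  expect_equal(got$in_consolidated, want$in_cons)
  # non-members carry empty source sets
  expect_true(all(lengths(got$sources[!got$in_rare]) == 0))
})

test_that("cross-flavour source concordance consolidates by default, and the strict switch does not", {
  # ICD-10 topography hit + NLP histology-only hit
  ds <- bind_cases(patient_case("P1", icd10_rare_claim = TRUE))
  ds$notes$text <- "Aspect d'un adénocarcinome.\nCode ADICAP : BHLA7080\n"
  ev <- collect_evidence(ds)
  expect_setequal(paste(ev$source, ev$flavour),
                  c("ICD10 rare_topography", "NLP rare_histology"))
  asg <- build_assignments(ds, ev)
  expect_true(asg$in_consolidated)
  strict <- build_assignments(ds, ev, concordance_within_flavour = TRUE)
  expect_false(strict$in_consolidated)
  # same-flavour agreement consolidates under both rules
  ds2 <- bind_cases(patient_case("P2", adicap_rare = TRUE, nlp_rare = TRUE))
  ev2 <- collect_evidence(ds2)
  expect_true(build_assignments(ds2, ev2)$in_consolidated)
  expect_true(build_assignments(ds2, ev2,
                                concordance_within_flavour = TRUE)$in_consolidated)
})

test_that("evidence outside the HNC cohort is dropped with a warning", {
  ds <- bind_cases(patient_case("P1"))
  ev <- tibble::tibble(person_id = c("P1", "PX"),
                       source = c("NLP", "NLP"),
                       flavour = "rare_histology",
                       provenance = "note:N@[0,1):x")
  expect_warning(asg <- build_assignments(ds, ev),
                 class = "rarehnc_evidence_dropped")
  expect_equal(asg$person_id, "P1")
  expect_true(asg$in_rare_histology)
})

test_that("ICD10 histology evidence is rejected as corrupt", {
  ds <- bind_cases(patient_case("P1"))
  ev <- tibble::tibble(person_id = "P1", source = "ICD10",
                       flavour = "rare_histology", provenance = "claim:C11")
  expect_error(build_assignments(ds, ev), class = "rarehnc_integrity_error")
})

test_that("structural invariants hold on random evidence configurations", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 30
    flags <- tibble::tibble(
      icd = stats::runif(n) < 0.3,
      adi = stats::runif(n) < 0.3,
      nlp = stats::runif(n) < 0.4,
      rep_ok = stats::runif(n) < 0.9
    )
    cases <- purrr::pmap(
      cbind(id = sprintf("R%02d", seq_len(n)), flags),
      function(id, icd, adi, nlp, rep_ok) {
        patient_case(id, icd10_rare_claim = icd, adicap_rare = adi,
                     nlp_rare = nlp, has_report = rep_ok)
      })
    ds <- do.call(bind_cases, cases)
    cohort <- build_hnc_cohort(ds)
    ev <- collect_evidence(ds, cohort)
    asg <- build_assignments(ds, ev, cohort)

    # inclusion chain: consolidated subset rare subset HNC cohort
    expect_true(all(asg$person_id[asg$in_consolidated] %in%
                      asg$person_id[asg$in_rare]))
    expect_true(all(asg$person_id %in% cohort$person_id))
    expect_true(all(asg$in_rare[asg$in_consolidated]))
    expect_true(all(asg$in_hnc[asg$in_rare]))
    # inclusion-exclusion of subcohort sizes
    expect_equal(sum(asg$in_rare),
                 sum(asg$in_rare_topography) + sum(asg$in_rare_histology) -
                   sum(asg$in_rare_topography & asg$in_rare_histology))
    # removing one source's evidence only shrinks the cohorts
    for (src in unique(ev$source)) {
      asg2 <- build_assignments(ds, ev[ev$source != src, ], cohort)
      expect_lte(sum(asg2$in_rare), sum(asg$in_rare))
      expect_lte(sum(asg2$in_consolidated), sum(asg$in_consolidated))
      expect_true(all(asg2$person_id[asg2$in_rare] %in%
                        asg$person_id[asg$in_rare]))
    }
  }
})

test_that("single-source evidence can never consolidate", {
  ds <- build_truth_dataset()
  cohort <- build_hnc_cohort(ds)
  ev <- collect_evidence(ds, cohort)
  for (src in c("ICD10", "ADICAP", "NLP")) {
    asg <- build_assignments(ds, ev[ev$source == src, ], cohort)
    expect_equal(sum(asg$in_consolidated), 0)
  }
})

test_that("source attribution partitions each cohort exactly", {
  asg <- tibble::tibble(
    person_id = c("A", "B", "C"),
    in_hnc = TRUE,
    in_rare_topography = c(TRUE, TRUE, TRUE),
    in_rare_histology = FALSE,
    in_rare = TRUE,
    in_consolidated = c(FALSE, FALSE, TRUE),
    sources = list("NLP", "NLP", c("ADICAP", "NLP"))
  )
  att <- source_attribution(asg)
  rare <- att[att$cohort == "rare", ]
  expect_setequal(rare$sources, c("NLP", "ADICAP+NLP"))
  expect_equal(rare$n[rare$sources == "NLP"], 2L)
  expect_equal(sum(rare$n), 3L)
  # conservation within every cohort
  for (co in unique(att$cohort)) {
    size <- switch(co,
                   rare = sum(asg$in_rare),
                   rare_topography = sum(asg$in_rare_topography),
                   rare_histology = sum(asg$in_rare_histology),
                   consolidated = sum(asg$in_consolidated))
    expect_equal(sum(att$n[att$cohort == co]), size)
  }
  expect_equal(nrow(source_attribution(asg[0, ])), 0)
})
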