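# Small in-code fixtures shared across test files.

tiny_persons <- function() {
  tibble::tibble(
    person_id = c("P1", "P2"),
    birth_year = c(1960L, NA),
    sex = c("male", "female")
  )
}

tiny_claims <- function() {
  tibble::tibble(
    person_id = c("P1", "P1", "P2"),
    icd10_code = c("C11", "C30.0", "E11"),
    diagnosis_position = c("primary", "associated", "related")
  )
}

tiny_notes <- function() {
  tibble::tibble(
    note_id = c("N1", "N2"),
    person_id = c("P1", "P2"),
    note_type = c("pathology_report", "mdm_report"),
    text = c("Code ADICAP : BHGS7092", "RCP : dossier discuté.")
  )
}

tiny_dataset <- function() {
  ehr_dataset(tiny_persons(), tiny_claims(), tiny_notes())
}

# one-patient dataset builder used by the cohort truth-table tests
patient_case <- function(id, icd10_rare_claim = FALSE, adicap_rare = FALSE,
                         nlp_rare = FALSE, has_report = TRUE) {
  persons <- tibble::tibble(person_id = id)
  claims <- tibble::tibble(
    person_id = id,
    icd10_code = if (icd10_rare_claim) "C11" else "C09",
    diagnosis_position = "primary"
  )
  text <- paste0(
    "Compte rendu.\n",
    if (nlp_rare) "Carcinome adénoïde kystique de la parotide. "
    else "Carcinome épidermoïde du larynx. ",
    "\nCode ADICAP : ",
    if (adicap_rare) "BHSI7092" else "BHLA7080", "\n"
  )
  notes <- if (has_report) {
    tibble::tibble(note_id = paste0(id, "-n"), person_id = id,
                   note_type = "pathology_report", text = text)
  } else NULL
  list(persons = persons, claims = claims, notes = notes)
}

# assemble several patient_case() lists into one dataset
bind_cases <- function(...) {
  cases <- list(...)
  ehr_dataset(
    dplyr::bind_rows(lapply(cases, `[[`, "persons")),
    dplyr::bind_rows(lapply(cases, `[[`, "claims")),
    dplyr::bind_rows(lapply(cases, `[[`, "notes"))
  )
}
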