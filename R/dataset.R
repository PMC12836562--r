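#' Normalize ICD-10 codes
#'
#' Hospital claims exports write ICD-10 codes with or without the dot
#' (`"C30.0"` vs `"C300"`) and in mixed case.  All engine logic operates on
#' the dot-free uppercase form, so codes are normalized once on ingest.
#'
#' @param x Character vector of ICD-10 codes.
#' @return Character vector of dot-free uppercase codes.
#' @examples
#' normalize_icd10(c("C30.0", "c11", " C07 "))
#' @export
normalize_icd10 <- function(x) {
  gsub(".", "", toupper(trimws(as_chr(x))), fixed = TRUE)
}

ICD10_PATTERN <- "^[A-Z][0-9]{2}[0-9A-Z]{0,2}$"
DIAG_POSITIONS <- c("primary", "related", "associated")
SEXES <- c("male", "female", "unknown")
NOTE_TYPES <- c("pathology_report", "mdm_report")

#' Assemble and validate an EHR dataset
#'
#' Bundles the three tables the pipeline consumes — persons, ICD-10 claims and
#' clinical notes — into a validated container.  Claims codes are normalized
#' with [normalize_icd10()]; referential integrity (every claim and note must
#' point at a known person) and the field-level invariants are enforced.
#'
#' @param persons Data frame with columns `person_id`, and optionally
#'   `birth_year` (integer year, `NA` allowed) and `sex`
#'   (`"male"`/`"female"`/`"unknown"`).
#' @param claims Data frame with columns `person_id`, `icd10_code`,
#'   `diagnosis_position` (`"primary"`, `"related"` or `"associated"`) and
#'   optionally `claim_date`.
#' @param notes Data frame with columns `note_id`, `person_id`, `note_type`
#'   (`"pathology_report"` or `"mdm_report"`), `text` and optionally
#'   `note_date`.
#' @return An object of class `ehr_dataset`: a list of the three validated
#'   tibbles.
#' @export
ehr_dataset <- function(persons, claims = NULL, notes = NULL) {
  persons <- as_tibble(persons)
  assert_columns(persons, "person_id", "persons")
  persons$person_id <- as_chr(persons$person_id)
  if (anyDuplicated(persons$person_id)) {
    dup <- unique(persons$person_id[duplicated(persons$person_id)])
    abort(sprintf("duplicated person_id in persons: %s",
                  paste(dup, collapse = ", ")),
          class = "rarehnc_integrity_error")
  }
  if (!"birth_year" %in% names(persons)) persons$birth_year <- NA_integer_
  persons$birth_year <- as.integer(persons$birth_year)
  if (!"sex" %in% names(persons)) persons$sex <- "unknown"
  persons$sex <- as_chr(persons$sex)
  bad_sex <- setdiff(unique(persons$sex[!is.na(persons$sex)]), SEXES)
  if (length(bad_sex) > 0) {
    abort(sprintf("invalid sex value(s): %s", paste(bad_sex, collapse = ", ")),
          class = "rarehnc_schema_error")
  }

  claims <- if (is.null(claims)) {
    tibble(person_id = character(), icd10_code = character(),
           diagnosis_position = character(), claim_date = character())
  } else as_tibble(claims)
  if (nrow(claims) > 0 || ncol(claims) > 0) {
    assert_columns(claims, c("person_id", "icd10_code", "diagnosis_position"),
                   "claims")
  }
  claims$person_id <- as_chr(claims$person_id)
  claims$icd10_code <- normalize_icd10(claims$icd10_code)
  claims$diagnosis_position <- as_chr(claims$diagnosis_position)
  if (!"claim_date" %in% names(claims)) claims$claim_date <- NA_character_
  bad_code <- claims$icd10_code[!grepl(ICD10_PATTERN, claims$icd10_code)]
  if (length(bad_code) > 0) {
    abort(sprintf("malformed ICD-10 code(s): %s",
                  paste(unique(bad_code), collapse = ", ")),
          class = "rarehnc_schema_error")
  }
  bad_pos <- setdiff(unique(claims$diagnosis_position), DIAG_POSITIONS)
  if (length(bad_pos) > 0 || anyNA(claims$diagnosis_position)) {
    abort(sprintf("invalid diagnosis_position value(s): %s",
                  paste(c(bad_pos, if (anyNA(claims$diagnosis_position)) "NA"),
                        collapse = ", ")),
          class = "rarehnc_schema_error")
  }

  notes <- if (is.null(notes)) {
    tibble(note_id = character(), person_id = character(),
           note_type = character(), text = character(),
           note_date = character())
  } else as_tibble(notes)
  if (nrow(notes) > 0 || ncol(notes) > 0) {
    assert_columns(notes, c("note_id", "person_id", "note_type", "text"),
                   "notes")
  }
  notes$note_id <- as_chr(notes$note_id)
  notes$person_id <- as_chr(notes$person_id)
  notes$note_type <- as_chr(notes$note_type)
  notes$text <- as_chr(notes$text)
  if (!"note_date" %in% names(notes)) notes$note_date <- NA_character_
  if (anyDuplicated(notes$note_id)) {
    dup <- unique(notes$note_id[duplicated(notes$note_id)])
    abort(sprintf("duplicated note_id in notes: %s", paste(dup, collapse = ", ")),
          class = "rarehnc_integrity_error")
  }
  bad_type <- setdiff(unique(notes$note_type), NOTE_TYPES)
  if (length(bad_type) > 0) {
    abort(sprintf("invalid note_type value(s): %s",
                  paste(bad_type, collapse = ", ")),
          class = "rarehnc_schema_error")
  }

  orphans <- unique(c(
    setdiff(claims$person_id, persons$person_id),
    setdiff(notes$person_id, persons$person_id)
  ))
  if (length(orphans) > 0) {
    abort(sprintf("claims/notes reference unknown person_id: %s",
                  paste(orphans, collapse = ", ")),
          class = "rarehnc_integrity_error")
  }

  structure(
    list(
      persons = persons[, c("person_id", "birth_year", "sex")],
      claims = claims[, c("person_id", "icd10_code", "diagnosis_position",
                          "claim_date")],
      notes = notes[, c("note_id", "person_id", "note_type", "text",
                        "note_date")]
    ),
    class = "ehr_dataset"
  )
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>\n")
  cat(sprintf("  persons: %d\n", nrow(x$persons)))
  cat(sprintf("  claims:  %d\n", nrow(x$claims)))
  cat(sprintf("  notes:   %d (%d pathology, %d MDM)\n",
              nrow(x$notes),
              sum(x$notes$note_type == "pathology_report"),
              sum(x$notes$note_type == "mdm_report")))
  invisible(x)
}

apply_schema <- function(df, mapping) {
  if (is.null(mapping)) return(df)
  for (canonical in names(mapping)) {
    actual <- mapping[[canonical]]
    if (!actual %in% names(df)) {
      abort(sprintf("mapped column '%s' (for '%s') not found", actual,
                    canonical),
            class = "rarehnc_schema_error")
    }
    names(df)[names(df) == actual] <- canonical
  }
  df
}

#' Read an EHR dataset from delimited files
#'
#' Reads the persons, claims and notes tables from CSV files (UTF-8, header
#' row) and validates them with [ehr_dataset()].  Column names can be remapped
#' through a schema configuration, either an R list or a YAML file with
#' top-level keys `persons`, `claims`, `notes`, each mapping canonical column
#' names to the names used in the files.
#'
#' @param persons_file,claims_file,notes_file Paths to the CSV files.
#'   `claims_file` and `notes_file` may be `NULL` for datasets without claims
#'   or notes.
#' @param schema Optional schema mapping: a named list (or path to a YAML
#'   file) whose entries `persons`, `claims` and `notes` map canonical column
#'   names to file column names.
#' @return A validated `ehr_dataset`.
#' @export
read_ehr_dataset <- function(persons_file, claims_file = NULL,
                             notes_file = NULL, schema = NULL) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  read_one <- function(path) {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  persons <- apply_schema(read_one(persons_file), schema$persons)
  claims <- if (is.null(claims_file)) NULL else {
    apply_schema(read_one(claims_file), schema$claims)
  }
  notes <- if (is.null(notes_file)) NULL else {
    apply_schema(read_one(notes_file), schema$notes)
  }
  ehr_dataset(persons, claims, notes)
}

#' Read gold annotations
#'
#' Gold labels carry the chart-review classification of each patient:
#' rare-topography and rare-histology status, with the overall rare-HNC flag
#' as their disjunction (recomputed, not trusted from the file).
#'
#' @param path CSV file with columns `person_id`, `is_rare_topography`,
#'   `is_rare_histology` (logical or 0/1).
#' @return Tibble with `person_id`, `is_rare_topography`, `is_rare_histology`,
#'   `is_rare_hnc`.
#' @export
read_gold <- function(path) {
  gold <- readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    .default = readr::col_logical()
  ), progress = FALSE)
  assert_columns(gold, c("person_id", "is_rare_topography", "is_rare_histology"),
                 "gold")
  gold %>%
    mutate(is_rare_hnc = .data$is_rare_topography | .data$is_rare_histology) %>%
    select("person_id", "is_rare_topography", "is_rare_histology",
           "is_rare_hnc")
}

#' Write and read cohort assignments
#'
#' Serializes a cohort-assignment table (see [build_assignments()]) to CSV.
#' The per-patient source set is rendered as a stable `+`-joined token
#' (e.g. `"ICD10+NLP"`, alphabetical order) so files diff cleanly;
#' `read_cohort()` restores the list-column.
#'
#' @param assignments Assignment tibble with a `sources` list-column.
#' @param path Output CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the assignment tibble.
#' @export
write_cohort <- function(assignments, path) {
  out <- assignments %>%
    mutate(sources = render_sources(.data$sources))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    sources = readr::col_character(),
    .default = readr::col_logical()
  ), progress = FALSE)
  x$sources[is.na(x$sources)] <- ""
  x %>% mutate(sources = parse_sources(.data$sources))
}
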