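match_codeset <- function(codes, set, prefix = TRUE) {
  if (!prefix) return(codes %in% set)
  out <- logical(length(codes))
  for (entry in set) {
    out <- out | codes == entry |
      startsWith(codes, entry)
  }
  out
}

#' Classify ICD-10 codes for HNC and rare-topography membership
#'
#' Prefix semantics: a code matches a set entry when it equals it or extends
#' it (`"C110"` matches `"C11"`).  A code counts as HNC when it matches the
#' HNC set or the rare-topography set (the rare list adds C41, C07, C08 to
#' the anatomical C00--C14 / C30--C32 core).  ICD-10 carries no histology
#' information, so there is no rare-histology flag here.
#'
#' @param codes Character vector of ICD-10 codes (any dialect; normalized
#'   internally).
#' @param codesets Code-set configuration from [read_codesets()].
#' @return Tibble with columns `icd10_code` (normalized), `is_hnc`,
#'   `is_rare_topography`.
#' @examples
#' classify_icd10(c("C11", "C30.0", "E11"))
#' @export
classify_icd10 <- function(codes, codesets = default_codesets()) {
  codes <- normalize_icd10(codes)
  bad <- codes[!grepl(ICD10_PATTERN, codes)]
  if (length(bad) > 0 || anyNA(codes)) {
    abort(sprintf("malformed ICD-10 code(s): %s",
                  paste(unique(c(bad, if (anyNA(codes)) "NA")), collapse = ", ")),
          class = "rarehnc_classification_error")
  }
  rare <- match_codeset(codes, codesets$rare_topography_codes,
                        codesets$prefix_matching)
  hnc <- match_codeset(codes, codesets$hnc_codes, codesets$prefix_matching) |
    rare
  tibble(icd10_code = codes, is_hnc = hnc, is_rare_topography = rare)
}

#' Patient-level ICD-10 HNC flags and rare-topography evidence
#'
#' `icd10_hnc_flags()` returns, per patient, whether at least one claim is an
#' HNC code in an admissible cohort position (default: primary or related
#' diagnosis).  `icd10_evidence()` emits one rare-topography evidence row per
#' patient with at least one rare-topography code in an admissible evidence
#' position (default: primary, related or associated — deliberately wider
#' than the cohort rule).  ICD-10 never produces rare-histology evidence.
#'
#' @param claims Claims tibble (`person_id`, `icd10_code`,
#'   `diagnosis_position`), e.g. `dataset$claims`.
#' @param codesets Code-set configuration from [read_codesets()].
#' @return `icd10_hnc_flags()`: tibble `person_id`, `icd10_hnc`.
#'   `icd10_evidence()`: evidence tibble with columns `person_id`, `source`
#'   (`"ICD10"`), `flavour` (`"rare_topography"`), `provenance` (the
#'   triggering code and position).
#' @export
icd10_evidence <- function(claims, codesets = default_codesets()) {
  if (nrow(claims) == 0) return(empty_evidence())
  cls <- classify_icd10(claims$icd10_code, codesets)
  hits <- claims %>%
    mutate(is_rare = cls$is_rare_topography) %>%
    filter(.data$is_rare,
           .data$diagnosis_position %in% codesets$rare_topo_positions) %>%
    group_by(.data$person_id) %>%
    slice(1) %>%
    ungroup()
  tibble(
    person_id = hits$person_id,
    source = rep("ICD10", nrow(hits)),
    flavour = rep("rare_topography", nrow(hits)),
    provenance = sprintf("claim:%s/%s", hits$icd10_code,
                         hits$diagnosis_position)
  )
}

#' @rdname icd10_evidence
#' @export
icd10_hnc_flags <- function(claims, codesets = default_codesets()) {
  if (nrow(claims) == 0) {
    return(tibble(person_id = character(), icd10_hnc = logical()))
  }
  cls <- classify_icd10(claims$icd10_code, codesets)
  claims %>%
    mutate(hit = cls$is_hnc &
             .data$diagnosis_position %in% codesets$hnc_positions) %>%
    group_by(.data$person_id) %>%
    summarise(icd10_hnc = any(.data$hit), .groups = "drop")
}

empty_evidence <- function() {
  tibble(person_id = character(), source = character(),
         flavour = character(), provenance = character())
}
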