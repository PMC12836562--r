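#' Extract ADICAP codes from pathology-report text
#'
#' ADICAP codes are 8-character alphanumeric tokens (four 2-character fields:
#' sample type, sample site, benign/malignant behaviour, histology type).
#' A candidate token is accepted only in a code context: either a cue (by
#' default the word "ADICAP", matched case-insensitively) appears earlier on
#' the same line, or the token stands alone on its line.  Tokens must contain
#' at least one letter, which keeps 8-digit accession numbers out.
#'
#' @param x Character vector of report texts.
#' @param dictionary ADICAP dictionary (supplies the cue pattern and field
#'   order); see [read_adicap_dictionary()].
#' @return Tibble with one row per code: `text_id` (index into `x`), `raw`,
#'   the four named fields, and 0-based half-open offsets `start`, `end`.
#' @examples
#' extract_adicap("Code ADICAP : BHGS7092")
#' @export
extract_adicap <- function(x, dictionary = default_adicap_dictionary()) {
  x <- as_chr(x)
  # line-based scan, vectorized over all lines of all texts: the code
  # context (cue earlier on the line, or code standing alone) is a
  # line-local property
  x0 <- ifelse(is.na(x), "", x)
  line_list <- strsplit(paste0(x0, "\n"), "\n", fixed = TRUE)
  n_lines <- lengths(line_list)
  lines <- unlist(line_list, use.names = FALSE)
  line_text_id <- rep(seq_along(x0), n_lines)
  # 0-based offset of each line within its text
  line_off <- unlist(lapply(line_list, function(ls) {
    cumsum(c(0L, nchar(ls) + 1L))[seq_along(ls)]
  }), use.names = FALSE)

  loc <- stringr::str_locate_all(
    lines, "(?<![A-Za-z0-9])[A-Z0-9]{8}(?![A-Za-z0-9])")
  counts <- vapply(loc, nrow, integer(1))
  if (sum(counts) > 0) {
    mm <- do.call(rbind, loc)
    line_id <- rep(seq_along(lines), counts)
    s <- unname(mm[, 1])
    raw <- substring(lines[line_id], s, s + 7L)
    before <- fold_text(substring(lines[line_id], 1L, s - 1L))
    keep <- grepl("[A-Z]", raw) &
      (grepl(dictionary$cue_pattern, before, perl = TRUE) |
         trimws(lines[line_id]) == raw)
    out <- tibble(
      text_id = line_text_id[line_id[keep]],
      raw = raw[keep],
      start = line_off[line_id[keep]] + s[keep] - 1L,
      end = line_off[line_id[keep]] + s[keep] + 7L
    )
  } else {
    out <- tibble(text_id = integer(), raw = character(),
                  start = integer(), end = integer())
  }
  if (nrow(out) == 0) {
    out <- tibble(text_id = integer(), raw = character(),
                  start = integer(), end = integer())
  }
  # slice the four 2-character fields in the configured order
  fo <- dictionary$field_order
  for (k in seq_along(fo)) {
    out[[fo[k]]] <- substring(out$raw, 2L * k - 1L, 2L * k)
  }
  out[, c("text_id", "raw", fo, "start", "end")]
}

lookup_field <- function(codes, map, flags) {
  idx <- match(codes, map$code)
  out <- tibble(label = ifelse(is.na(idx), "UNKNOWN", map$label[idx]))
  for (f in flags) {
    out[[f]] <- !is.na(idx) & map[[f]][idx]
  }
  out
}

#' Decode ADICAP codes against a dictionary
#'
#' Field-wise lookup: the site field yields a label plus HNC and
#' rare-topography flags, the behaviour field the malignancy flag, the
#' histology field the SCC flag.  Codes absent from a map decode to
#' `"UNKNOWN"` with all flags `FALSE` — an unknown site can never assert HNC
#' membership.
#'
#' @param codes Tibble from [extract_adicap()] (needs columns `site`,
#'   `behaviour`, `histology`).
#' @param dictionary ADICAP dictionary; see [read_adicap_dictionary()].
#' @return The input with added columns `site_label`, `is_hnc`,
#'   `is_rare_topography`, `is_malignant`, `histology_label`, `is_scc`.
#' @export
decode_adicap <- function(codes, dictionary = default_adicap_dictionary()) {
  site <- lookup_field(codes$site, dictionary$sites,
                       c("is_hnc", "is_rare_topography"))
  beh <- lookup_field(codes$behaviour, dictionary$behaviours, "is_malignant")
  his <- lookup_field(codes$histology, dictionary$histologies, "is_scc")
  codes$site_label <- site$label
  codes$is_hnc <- site$is_hnc
  codes$is_rare_topography <- site$is_rare_topography
  codes$is_malignant <- beh$is_malignant
  codes$histology_label <- his$label
  codes$is_scc <- his$is_scc
  codes
}

#' ADICAP-source evidence and HNC flags per patient
#'
#' Evidence is computed from pathology reports only (MDM notes are never
#' mined).  A patient gets rare-histology ADICAP evidence when some decoded
#' code is malignant, in an HNC site, and not SCC; rare-topography evidence
#' when some code is in a rare-topography site (by default additionally
#' gated on malignancy, since benign lesions of a rare site are not rare
#' cancers); `adicap_hnc` is true when some code is malignant in an HNC
#' site.
#'
#' @param notes Notes tibble (`note_id`, `person_id`, `note_type`, `text`).
#'   Non-pathology rows are ignored.
#' @param dictionary ADICAP dictionary; see [read_adicap_dictionary()].
#' @param require_malignant_for_topo Gate rare-topography evidence on
#'   malignant behaviour (default `TRUE`).
#' @return `adicap_evidence()`: evidence tibble (`person_id`, `source` =
#'   `"ADICAP"`, `flavour`, `provenance` carrying note id, span and raw
#'   code).  `adicap_hnc_flags()`: tibble `person_id`, `adicap_hnc`.
#' @export
adicap_evidence <- function(notes, dictionary = default_adicap_dictionary(),
                            require_malignant_for_topo = TRUE) {
  dec <- decode_patient_codes(notes, dictionary)
  if (nrow(dec) == 0) return(empty_evidence())
  dec <- dec %>%
    mutate(
      topo_hit = .data$is_rare_topography &
        (!require_malignant_for_topo | .data$is_malignant),
      histo_hit = .data$is_malignant & .data$is_hnc & !.data$is_scc,
      provenance = sprintf("note:%s@[%d,%d):%s", .data$note_id, .data$start,
                           .data$end, .data$raw)
    )
  bind_rows(
    dec %>% filter(.data$topo_hit) %>%
      group_by(.data$person_id) %>% slice(1) %>% ungroup() %>%
      transmute(.data$person_id, source = "ADICAP",
                flavour = "rare_topography", .data$provenance),
    dec %>% filter(.data$histo_hit) %>%
      group_by(.data$person_id) %>% slice(1) %>% ungroup() %>%
      transmute(.data$person_id, source = "ADICAP",
                flavour = "rare_histology", .data$provenance)
  ) %>% arrange(.data$person_id, .data$flavour)
}

#' @rdname adicap_evidence
#' @export
adicap_hnc_flags <- function(notes, dictionary = default_adicap_dictionary()) {
  with_report <- notes %>%
    filter(.data$note_type == "pathology_report") %>%
    distinct(.data$person_id)
  dec <- decode_patient_codes(notes, dictionary)
  hit <- dec %>%
    group_by(.data$person_id) %>%
    summarise(adicap_hnc = any(.data$is_malignant & .data$is_hnc),
              .groups = "drop")
  with_report %>%
    left_join(hit, by = "person_id") %>%
    mutate(adicap_hnc = coalesce(.data$adicap_hnc, FALSE))
}

decode_patient_codes <- function(notes, dictionary) {
  path <- notes %>% filter(.data$note_type == "pathology_report")
  if (nrow(path) == 0) {
    return(tibble(person_id = character(), note_id = character(),
                  raw = character(), start = integer(), end = integer(),
                  is_hnc = logical(), is_rare_topography = logical(),
                  is_malignant = logical(), is_scc = logical()))
  }
  codes <- extract_adicap(path$text, dictionary)
  if (nrow(codes) == 0) {
    return(tibble(person_id = character(), note_id = character(),
                  raw = character(), start = integer(), end = integer(),
                  is_hnc = logical(), is_rare_topography = logical(),
                  is_malignant = logical(), is_scc = logical()))
  }
  codes %>%
    decode_adicap(dictionary) %>%
    mutate(person_id = path$person_id[.data$text_id],
           note_id = path$note_id[.data$text_id])
}
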