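pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rarehnc")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ may be on the path directly
    path <- system.file(file.path("inst", "extdata", file), package = "rarehnc")
  }
  if (!nzchar(path)) abort(sprintf("shipped config '%s' not found", file))
  path
}

#' Load ICD-10 code-set configuration
#'
#' The code sets drive [classify_icd10()] and [icd10_evidence()]: which
#' prefixes count as head-and-neck cancer, which as rare topography, and
#' which diagnosis positions are admissible for each purpose.  The shipped
#' default reproduces the rare-topography list
#' C07, C08, C11, C41, C300, C301, C31 verbatim and uses C00--C14 plus
#' C30--C32 for HNC membership.
#'
#' @param path YAML file; `NULL` loads the shipped default.
#' @return A list with elements `hnc_codes`, `rare_topography_codes`,
#'   `hnc_positions`, `rare_topo_positions`, `prefix_matching`.
#' @export
read_codesets <- function(path = NULL) {
  path <- path %||% pkg_extdata("codesets.yaml")
  cfg <- yaml::read_yaml(path)
  for (k in c("hnc_codes", "rare_topography_codes", "hnc_positions",
              "rare_topo_positions")) {
    if (is.null(cfg[[k]]) || length(cfg[[k]]) == 0) {
      abort(sprintf("codesets config: '%s' must be non-empty", k),
            class = "rarehnc_config_error")
    }
  }
  bad_pos <- setdiff(c(cfg$hnc_positions, cfg$rare_topo_positions),
                     DIAG_POSITIONS)
  if (length(bad_pos) > 0) {
    abort(sprintf("codesets config: unknown diagnosis position(s): %s",
                  paste(bad_pos, collapse = ", ")),
          class = "rarehnc_config_error")
  }
  cfg$hnc_codes <- normalize_icd10(cfg$hnc_codes)
  cfg$rare_topography_codes <- normalize_icd10(cfg$rare_topography_codes)
  cfg$prefix_matching <- cfg$prefix_matching %||% TRUE
  cfg
}

#' @rdname read_codesets
#' @export
default_codesets <- function() read_codesets(NULL)

#' Load an ADICAP decoding dictionary
#'
#' The dictionary maps each 2-character field of an 8-character ADICAP code
#' to its semantics: site codes carry HNC membership and topographic rarity,
#' behaviour codes carry malignancy, histology codes carry the SCC flag.
#' The shipped file is a small synthetic fixture, not the official
#' thesaurus; codes absent from a map decode to an explicit `"UNKNOWN"`
#' record with all flags `FALSE`.
#'
#' @param path YAML file; `NULL` loads the shipped synthetic fixture.
#' @return A list with tibbles `sites`, `behaviours`, `histologies`,
#'   `sample_types`, plus `field_order` and `cue_pattern`.
#' @export
read_adicap_dictionary <- function(path = NULL) {
  path <- path %||% pkg_extdata("adicap_dictionary.yaml")
  cfg <- yaml::read_yaml(path)
  map_tbl <- function(m, flags) {
    out <- purrr::imap_dfr(m, function(v, code) {
      if (is.character(v)) v <- list(label = v)
      row <- tibble(code = code, label = v$label %||% code)
      for (f in flags) row[[f]] <- isTRUE(v[[f]])
      row
    })
    if (any(nchar(out$code) != 2)) {
      abort("ADICAP dictionary: all field codes must be 2 characters",
            class = "rarehnc_config_error")
    }
    out
  }
  list(
    field_order = unlist(cfg$field_order %||%
                           c("sample_type", "site", "behaviour", "histology")),
    cue_pattern = cfg$cue_pattern %||% "adicap",
    sample_types = map_tbl(cfg$sample_types, character()),
    sites = map_tbl(cfg$sites, c("is_hnc", "is_rare_topography")),
    behaviours = map_tbl(cfg$behaviours, "is_malignant"),
    histologies = map_tbl(cfg$histologies, "is_scc")
  )
}

#' @rdname read_adicap_dictionary
#' @export
default_adicap_dictionary <- function() read_adicap_dictionary(NULL)

#' Load the mention lexicon
#'
#' Each entry is a regular expression (written in unaccented lowercase; the
#' matcher folds the text the same way) with a category (`topography` or
#' `histology`), a canonical concept label, and a rarity flag.
#'
#' @param path YAML file; `NULL` loads the shipped French fixture lexicon.
#' @return Tibble with columns `pattern`, `category`, `label`, `is_rare`.
#' @export
read_lexicon <- function(path = NULL) {
  path <- path %||% pkg_extdata("lexicon.yaml")
  cfg <- yaml::read_yaml(path)
  lex <- purrr::map_dfr(cfg$entries, ~ tibble(
    pattern = .x$pattern, category = .x$category,
    label = .x$label, is_rare = isTRUE(.x$is_rare)
  ))
  bad_cat <- setdiff(unique(lex$category), c("topography", "histology"))
  if (length(bad_cat) > 0) {
    abort(sprintf("lexicon: unknown category: %s",
                  paste(bad_cat, collapse = ", ")),
          class = "rarehnc_config_error")
  }
  dup <- lex %>% count(.data$category, .data$label) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("lexicon: duplicated label(s) within category: %s",
                  paste(dup$label, collapse = ", ")),
          class = "rarehnc_config_error")
  }
  # fail fast on uncompilable patterns
  purrr::walk(lex$pattern, ~ regexpr(.x, "", perl = TRUE))
  lex
}

#' Load qualifier trigger configuration
#'
#' Triggers implement ConText-style qualification: each has a pattern, a
#' direction (`forward` = trigger precedes the mention, `backward` = trigger
#' follows it) and a token scope bounding its reach within the sentence.
#'
#' @param path YAML file; `NULL` loads the shipped French fixture triggers.
#' @return Tibble with columns `qualifier`, `pattern`, `direction`, `scope`.
#' @export
read_triggers <- function(path = NULL) {
  path <- path %||% pkg_extdata("triggers.yaml")
  cfg <- yaml::read_yaml(path)
  trg <- purrr::imap_dfr(cfg, function(entries, qualifier) {
    purrr::map_dfr(entries, ~ tibble(
      qualifier = qualifier, pattern = .x$pattern,
      direction = .x$direction %||% "forward",
      scope = as.integer(.x$scope %||% 8L)
    ))
  })
  bad_q <- setdiff(unique(trg$qualifier), c("negation", "hypothesis", "history"))
  if (length(bad_q) > 0) {
    abort(sprintf("triggers: unknown qualifier section: %s",
                  paste(bad_q, collapse = ", ")),
          class = "rarehnc_config_error")
  }
  bad_d <- setdiff(unique(trg$direction), c("forward", "backward"))
  if (length(bad_d) > 0 || any(!is.finite(trg$scope))) {
    abort("triggers: every trigger needs a direction in {forward, backward} and a finite scope",
          class = "rarehnc_config_error")
  }
  purrr::walk(trg$pattern, ~ regexpr(.x, "", perl = TRUE))
  trg
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() read_lexicon(NULL)

#' @rdname read_triggers
#' @export
default_triggers <- function() read_triggers(NULL)
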