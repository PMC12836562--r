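#' Segment text into sentences
#'
#' Sentence boundaries are the terminators `". "`, newline, `"!"` and `"?"`.
#' Spans are 0-based half-open offsets into the original text; segments that
#' contain only whitespace are dropped, so no empty sentences are returned.
#' Qualifier scoping is bounded by these spans.
#'
#' @param text A single string.
#' @return Tibble with columns `start`, `end` (0-based half-open).
#' @examples
#' segment_sentences("Pas de tumeur. Biopsie du sinus.")
#' @export
segment_sentences <- function(text) {
  stopifnot(length(text) == 1)
  empty <- tibble(start = integer(), end = integer())
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("\\. |\n|!|\\?", text)[[1]]
  n <- nchar(text)
  if (m[1] == -1) {
    bounds <- n
  } else {
    bounds <- unique(c(as.integer(m) + attr(m, "match.length") - 1L, n))
  }
  starts <- c(0L, bounds[-length(bounds)])
  out <- tibble(start = as.integer(starts), end = as.integer(bounds))
  keep <- vapply(seq_len(nrow(out)), function(i) {
    nzchar(trimws(substring(text, out$start[i] + 1L, out$end[i])))
  }, logical(1))
  out[keep, ]
}

# Vectorized lexicon matching over many texts.  Returns 1-based start/end
# (inclusive) internally; public functions convert to 0-based half-open.
match_lexicon_many <- function(texts, lexicon) {
  folded <- fold_text(texts)
  hits <- purrr::imap_dfr(lexicon$pattern, function(pat, j) {
    loc <- stringr::str_locate_all(
      folded, stringr::regex(paste0("\\b(?:", pat, ")\\b"))
    )
    counts <- vapply(loc, nrow, integer(1))
    if (sum(counts) == 0) return(NULL)
    mm <- do.call(rbind, loc)
    tibble(text_id = rep(seq_along(loc), counts),
           s = unname(mm[, 1]), e = unname(mm[, 2]), entry = j)
  })
  if (nrow(hits) == 0) {
    return(tibble(text_id = integer(), start = integer(), end = integer(),
                  surface = character(), category = character(),
                  label = character(), is_rare = logical()))
  }
  # longest-match-wins at equal start, earlier-start-wins on overlap
  hits <- hits %>%
    mutate(len = .data$e - .data$s) %>%
    arrange(.data$text_id, .data$s, desc(.data$len), .data$entry)
  keep <- logical(nrow(hits))
  last_text <- -1L; last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$text_id[i] != last_text) { last_text <- hits$text_id[i]; last_end <- 0L }
    if (hits$s[i] > last_end) { keep[i] <- TRUE; last_end <- hits$e[i] }
  }
  hits <- hits[keep, ]
  tibble(
    text_id = hits$text_id,
    start = hits$s - 1L,
    end = hits$e,
    surface = substring(texts[hits$text_id], hits$s, hits$e),
    category = lexicon$category[hits$entry],
    label = lexicon$label[hits$entry],
    is_rare = lexicon$is_rare[hits$entry]
  )
}

#' Match a lexicon against text
#'
#' Finds all non-overlapping lexicon matches (longest match wins at equal
#' start; on overlap the earlier start wins), case- and accent-insensitively:
#' both the text and the patterns are lowercased and accent-folded before
#' matching, so offsets refer to the original text.
#'
#' @param text A single string.
#' @param lexicon Lexicon tibble from [read_lexicon()].
#' @return Tibble of unqualified mentions: `start`, `end` (0-based
#'   half-open), `surface`, `category`, `label`, `is_rare`.
#' @export
match_lexicon <- function(text, lexicon = default_lexicon()) {
  stopifnot(length(text) == 1)
  match_lexicon_many(text, lexicon) %>% select(-"text_id")
}

# Qualify mentions (with text_id, 0-based start/end) against their sentence
# context.  Adds logical columns negated / hypothesis / history.
qualify_many <- function(mentions, texts, triggers) {
  mentions$negated <- FALSE
  mentions$hypothesis <- FALSE
  mentions$history <- FALSE
  if (nrow(mentions) == 0) return(mentions)
  folded <- fold_text(texts)
  # locate the sentence containing each mention, one segmentation per text
  sent_start <- integer(nrow(mentions))
  sent_end <- integer(nrow(mentions))
  by_text <- split(seq_len(nrow(mentions)), mentions$text_id)
  for (tid_chr in names(by_text)) {
    rows <- by_text[[tid_chr]]
    tid <- as.integer(tid_chr)
    ss <- segment_sentences(texts[[tid]])
    for (i in rows) {
      j <- which(ss$start <= mentions$start[i] & mentions$start[i] < ss$end)
      if (length(j) == 0) {
        sent_start[i] <- mentions$start[i]; sent_end[i] <- mentions$end[i]
      } else {
        sent_start[i] <- ss$start[j[1]]; sent_end[i] <- ss$end[j[1]]
      }
    }
  }
  sent_folded <- substring(folded[mentions$text_id], sent_start + 1L, sent_end)
  # mention offsets relative to sentence (1-based inclusive)
  rel_s <- mentions$start - sent_start + 1L
  rel_e <- mentions$end - sent_start
  qual_col <- c(negation = "negated", hypothesis = "hypothesis",
                history = "history")
  for (k in seq_len(nrow(triggers))) {
    trg <- triggers[k, ]
    col <- qual_col[[trg$qualifier]]
    todo <- which(!mentions[[col]])
    if (length(todo) == 0) next
    loc <- stringr::str_locate_all(sent_folded[todo],
                                   stringr::regex(trg$pattern))
    fired <- vapply(seq_along(todo), function(ii) {
      mm <- loc[[ii]]
      if (nrow(mm) == 0) return(FALSE)
      i <- todo[ii]
      if (trg$direction == "forward") {
        ok <- mm[, 2] < rel_s[i]
        if (!any(ok)) return(FALSE)
        gaps <- substring(sent_folded[i], mm[ok, 2] + 1L, rel_s[i] - 1L)
      } else {
        ok <- mm[, 1] > rel_e[i]
        if (!any(ok)) return(FALSE)
        gaps <- substring(sent_folded[i], rel_e[i] + 1L, mm[ok, 1] - 1L)
      }
      any(stringr::str_count(gaps, "\\S+") <= trg$scope)
    }, logical(1))
    mentions[[col]][todo[fired]] <- TRUE
  }
  mentions
}

#' Qualify a mention against its sentence context
#'
#' Sets the `negated`, `hypothesis` and `history` qualifiers of each mention:
#' a qualifier is true when a matching trigger occurs in the same sentence,
#' on the trigger's side of the mention (forward triggers precede it,
#' backward triggers follow it), within the trigger's token scope.
#' Qualifiers are independent; spans and labels are never altered.
#'
#' @param mentions Mention tibble from [match_lexicon()] (same text).
#' @param text The single source string the mentions were found in.
#' @param triggers Trigger tibble from [read_triggers()].
#' @return `mentions` with logical columns `negated`, `hypothesis`,
#'   `history` added.
#' @export
qualify_mentions <- function(mentions, text, triggers = default_triggers()) {
  stopifnot(length(text) == 1)
  mentions$text_id <- rep(1L, nrow(mentions))
  out <- qualify_many(mentions, text, triggers)
  out %>% select(-"text_id")
}

#' Extract qualified mentions from clinical notes
#'
#' Runs lexicon matching and qualification over the pathology reports of a
#' notes table (MDM notes are never mined).
#'
#' @param notes Notes tibble (`note_id`, `person_id`, `note_type`, `text`).
#' @param lexicon Lexicon tibble; see [read_lexicon()].
#' @param triggers Trigger tibble; see [read_triggers()].
#' @return Tibble of mentions with `note_id`, `person_id`, spans, labels,
#'   rarity and qualifier columns, plus `asserted` (no qualifier set).
#' @export
note_mentions <- function(notes, lexicon = default_lexicon(),
                          triggers = default_triggers()) {
  path <- notes %>% filter(.data$note_type == "pathology_report")
  mentions <- match_lexicon_many(path$text, lexicon)
  mentions <- qualify_many(mentions, path$text, triggers)
  mentions %>%
    mutate(note_id = path$note_id[.data$text_id],
           person_id = path$person_id[.data$text_id],
           asserted = !.data$negated & !.data$hypothesis & !.data$history) %>%
    select("note_id", "person_id", "start", "end", "surface", "category",
           "label", "is_rare", "negated", "hypothesis", "history", "asserted")
}

#' NLP-source evidence per patient
#'
#' A patient gets rare-topography NLP evidence when at least one asserted
#' (not negated, not hypothetical, not historical) rare topography mention
#' occurs in any of their pathology reports, and rare-histology evidence
#' likewise for rare histology mentions.  Evidence is patient-level and
#' deduplicated per flavour; provenance records the first triggering
#' mention.
#'
#' @inheritParams note_mentions
#' @param histology_requires_hnc_context If `TRUE`, a rare-histology mention
#'   only counts when a topography mention occurs in the same note (default
#'   `FALSE`: reports reaching this stage are already HNC-filtered
#'   upstream).
#' @return Evidence tibble (`person_id`, `source` = `"NLP"`, `flavour`,
#'   `provenance`).
#' @export
nlp_evidence <- function(notes, lexicon = default_lexicon(),
                         triggers = default_triggers(),
                         histology_requires_hnc_context = FALSE) {
  mentions <- note_mentions(notes, lexicon, triggers)
  hits <- mentions %>% filter(.data$asserted, .data$is_rare)
  if (histology_requires_hnc_context) {
    topo_notes <- mentions %>%
      filter(.data$category == "topography") %>%
      pull(.data$note_id) %>% unique()
    hits <- hits %>%
      filter(.data$category == "topography" | .data$note_id %in% topo_notes)
  }
  if (nrow(hits) == 0) return(empty_evidence())
  hits %>%
    mutate(flavour = ifelse(.data$category == "topography",
                            "rare_topography", "rare_histology"),
           provenance = sprintf("note:%s@[%d,%d):%s", .data$note_id,
                                .data$start, .data$end, .data$surface)) %>%
    group_by(.data$person_id, .data$flavour) %>%
    slice(1) %>%
    ungroup() %>%
    transmute(.data$person_id, source = "NLP", .data$flavour,
              .data$provenance) %>%
    arrange(.data$person_id, .data$flavour)
}
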