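#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Accent folding restricted to 1:1 Latin substitutions so character offsets
# into the original text stay valid after normalization.
ACCENTED <- "àâäéèêëîïôöùûüçÀÂÄÉÈÊËÎÏÔÖÙÛÜÇ"
PLAIN    <- "aaaeeeeiioouuucAAAEEEEIIOOUUUC"

#' Fold case and accents for matching
#'
#' Lowercases and strips French diacritics character-for-character, so that a
#' position in the folded string is the same position in the original string.
#'
#' @param x Character vector.
#' @return Character vector of the same length and per-element width.
#' @keywords internal
fold_text <- function(x) {
  tolower(chartr(ACCENTED, PLAIN, x))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "rarehnc_schema_error")
  }
  invisible(df)
}

as_chr <- function(x) {
  if (is.factor(x)) as.character(x) else as.character(x)
}

# Stable rendering of a source set as a single token, e.g. "ADICAP+ICD10+NLP".
SOURCE_LEVELS <- c("ADICAP", "ICD10", "NLP")

render_sources <- function(sources) {
  vapply(sources, function(s) {
    s <- intersect(SOURCE_LEVELS, unique(s))
    paste(s, collapse = "+")
  }, character(1))
}

parse_sources <- function(x) {
  lapply(strsplit(as_chr(x), "+", fixed = TRUE), function(s) {
    intersect(SOURCE_LEVELS, s)
  })
}
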