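# Utterance cleaning and tokenization.
#
# Cleaning mirrors common practice for Wizard-of-Oz interview transcripts:
# bracketed annotation spans (artificial conversation markers that were never
# spoken) are stripped first, then basic punctuation characters are deleted,
# then text is lowercased. Stop words are retained by default: several
# features count them, and removing them degrades downstream classification.

#' Cleaning rules for interview utterances
#'
#' @param lowercase Convert text to lower case (default `TRUE`).
#' @param punctuation_chars Characters deleted from the text (single
#'   characters; deletion, not token splitting). The default covers basic
#'   punctuation including `,` `.` `[` `]`; apostrophes are kept so
#'   contractions remain single words.
#' @param marker_patterns Regular expressions whose whole matches are removed
#'   before punctuation handling. Defaults cover square-bracketed,
#'   angle-bracketed and parenthesised annotation spans.
#' @param stopword_removal Optionally drop `stopwords` after cleaning
#'   (default `FALSE`; retained words are needed by the filler-word feature).
#' @param stopwords Words to drop when `stopword_removal` is `TRUE`.
#'
#' @return An object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(lowercase = TRUE,
                           punctuation_chars = c(",", ".", "[", "]", "?",
                                                 "!", ";", ":", "\""),
                           marker_patterns = c("\\[[^][]*\\]", "<[^<>]*>",
                                               "\\([^()]*\\)"),
                           stopword_removal = FALSE,
                           stopwords = character()) {
  stopifnot(is.logical(lowercase), is.character(punctuation_chars),
            is.character(marker_patterns), is.logical(stopword_removal),
            is.character(stopwords))
  structure(
    list(lowercase = lowercase,
         punctuation_chars = punctuation_chars,
         marker_patterns = marker_patterns,
         stopword_removal = stopword_removal,
         stopwords = stopwords),
    class = "cleaning_rules"
  )
}

#' Clean an utterance
#'
#' Removes annotation-marker spans, deletes punctuation characters,
#' lowercases, optionally removes stop words, and normalises whitespace.
#' Idempotent: cleaning a cleaned string is a no-op.
#'
#' @param text Character vector of raw utterances.
#' @param rules A [cleaning_rules()] object.
#'
#' @return Character vector of cleaned utterances.
#' @export
#' @examples
#' clean_utterance("Hello, World. [laughter]")
clean_utterance <- function(text, rules = cleaning_rules()) {
  stopifnot(is.character(text), inherits(rules, "cleaning_rules"))
  out <- text
  for (pat in rules$marker_patterns) {
    out <- gsub(pat, " ", out, perl = TRUE)
  }
  if (length(rules$punctuation_chars) > 0) {
    cls <- paste0("[", paste0("\\", rules$punctuation_chars, collapse = ""),
                  "]")
    out <- gsub(cls, "", out, perl = TRUE)
  }
  if (rules$lowercase) out <- tolower(out)
  if (rules$stopword_removal && length(rules$stopwords) > 0) {
    out <- vapply(out, function(s) {
      toks <- tokenize(s)
      paste(toks[!(toks %in% rules$stopwords)], collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
  out <- gsub("\\s+", " ", out, perl = TRUE)
  trimws(out)
}

#' Tokenize cleaned text
#'
#' Splits on runs of whitespace, preserving order. A word is a maximal
#' non-whitespace run; apostrophes stay inside tokens ("what's" is one word).
#'
#' @param text A single cleaned string.
#'
#' @return Character vector of tokens (length 0 for empty/whitespace input).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}
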