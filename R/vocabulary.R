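# Closed word lists shared by the synthetic corpus generator and the default
# feature-extraction components. Partitioning the vocabulary into
# sentiment-bearing, first-person, filler and neutral (POS-tagged) words makes
# every feature in the bank analytically checkable on generated corpora.

.vocab <- list(
  positive   = c("good", "great", "happy", "fine", "wonderful", "calm",
                 "hopeful", "glad"),
  negative   = c("bad", "sad", "tired", "awful", "terrible", "lonely",
                 "worried", "empty"),
  first_person = c("i", "we", "us", "me", "my", "myself"),
  filler     = c("uh", "um", "mm"),
  noun       = c("work", "family", "music", "city", "job", "friend", "house",
                 "dog", "school", "weekend"),
  verb       = c("think", "go", "know", "make", "talk", "sleep", "try",
                 "stay"),
  adjective  = c("big", "small", "old", "new", "long", "quiet"),
  adverb     = c("really", "very", "slowly", "usually", "often")
)

#' Default canonical question pool
#'
#' The nine interviewer questions that recur across published per-question
#' sentiment features for this interview style, padded with ten further
#' generic interview questions to reach the nineteen per-question feature
#' slots of the feature bank.
#'
#' @return Character vector of 19 question strings.
#' @export
default_question_pool <- function() {
  c(
    "what's your dream job",
    "do you consider yourself an introvert",
    "how are you at controlling your temper",
    "when was the last time you argued with someone and what was it about",
    "what do you do to relax",
    "how close are you to your family",
    "is there anything you regret",
    "what's one of your most memorable experiences",
    "when was the last time you felt really happy",
    "how are you doing today",
    "where are you from originally",
    "what are some things you really like about your city",
    "what did you study at school",
    "tell me about your best friend",
    "how easy is it for you to get a good night's sleep",
    "what do you enjoy about your work",
    "tell me about the last time you felt proud",
    "how would your best friend describe you",
    "what advice would you give to yourself ten years ago"
  )
}

#' Default sentiment lexicon
#'
#' A small word-to-polarity map into \[-1, 1\] covering the generator's
#' sentiment-bearing vocabulary. The sentiment scorer is pluggable, so a
#' production lexicon engine can be swapped in for real transcripts.
#'
#' @return Named numeric vector: word -> polarity.
#' @export
default_lexicon <- function() {
  c(
    stats::setNames(rep(1, length(.vocab$positive)), .vocab$positive),
    stats::setNames(rep(-1, length(.vocab$negative)), .vocab$negative)
  )
}

#' Default filler-word list
#'
#' Non-expressive spoken tokens ("uh", "um", "mm") counted by the
#' `avg_sw_frequency` feature.
#'
#' @return Character vector.
#' @export
default_filler_words <- function() .vocab$filler

#' Default first-person word list
#'
#' @return Character vector of first-person-related words.
#' @export
default_fp_words <- function() .vocab$first_person

#' Default deterministic dictionary part-of-speech tagger
#'
#' Maps each token to one of `noun`, `verb`, `adjective`, `adverb` or
#' `other` by dictionary lookup over the closed vocabulary (sentiment words
#' tag as adjectives). The tagger is pluggable: any
#' `function(tokens) -> character vector of roles` can replace it for real
#' transcripts.
#'
#' @return A tagging function.
#' @export
default_tagger <- function() {
  dict <- c(
    stats::setNames(rep("noun", length(.vocab$noun)), .vocab$noun),
    stats::setNames(rep("verb", length(.vocab$verb)), .vocab$verb),
    stats::setNames(rep("adjective",
                        length(.vocab$adjective) + length(.vocab$positive) +
                          length(.vocab$negative)),
                    c(.vocab$adjective, .vocab$positive, .vocab$negative)),
    stats::setNames(rep("adverb", length(.vocab$adverb)), .vocab$adverb)
  )
  function(tokens) {
    roles <- unname(dict[tokens])
    roles[is.na(roles)] <- "other"
    roles
  }
}
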