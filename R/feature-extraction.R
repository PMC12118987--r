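# The 30-feature bank: 19 per-question answer-sentiment features plus 11
# global speech/lexical features per session. A "comment" is one participant
# turn. All per-comment features are unweighted means of per-comment ratios.

GLOBAL_FEATURES <- c("avg_sentiment", "avg_response_time", "speech_speed",
                     "avg_unique_frequency", "avg_sw_frequency",
                     "avg_characters", "avg_nouns", "avg_verbs", "adj_freq",
                     "avg_adv", "fp_avg")

#' Feature-bank specification
#'
#' Bundles the pluggable components that define the feature bank: the
#' canonical question pool (one answer-sentiment feature per question), the
#' sentiment lexicon, the part-of-speech tagger, the filler- and
#' first-person word lists, and the cleaning rules.
#'
#' @param question_pool Character vector of canonical question strings
#'   (default: the 19-question pool, giving 19 + 11 = 30 features).
#' @param lexicon Named numeric vector mapping words to polarities in
#'   \[-1, 1\].
#' @param tagger Function `tokens -> roles` returning one of `"noun"`,
#'   `"verb"`, `"adjective"`, `"adverb"`, `"other"` per token.
#' @param filler_words Words counted by `avg_sw_frequency`.
#' @param fp_words First-person words counted by `fp_avg`.
#' @param rules [cleaning_rules()] applied to utterances before counting.
#' @param whole_interview_sentiment If `TRUE` (default) `avg_sentiment`
#'   scores the concatenation of all participant turns as one text;
#'   if `FALSE` it averages per-comment scores.
#'
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(question_pool = default_question_pool(),
                         lexicon = default_lexicon(),
                         tagger = default_tagger(),
                         filler_words = default_filler_words(),
                         fp_words = default_fp_words(),
                         rules = cleaning_rules(),
                         whole_interview_sentiment = TRUE) {
  stopifnot(is.character(question_pool), !anyDuplicated(question_pool),
            is.numeric(lexicon), !is.null(names(lexicon)),
            all(lexicon >= -1 & lexicon <= 1),
            is.function(tagger), is.character(filler_words),
            is.character(fp_words), inherits(rules, "cleaning_rules"))
  if (any(question_pool %in% GLOBAL_FEATURES)) {
    abort_depscreen("question names clash with global feature names",
                    "depscreen_config_error")
  }
  structure(list(question_pool = question_pool, lexicon = lexicon,
                 tagger = tagger, filler_words = filler_words,
                 fp_words = fp_words, rules = rules,
                 whole_interview_sentiment = whole_interview_sentiment),
            class = "feature_spec")
}

#' Names of all features defined by a spec
#'
#' @param spec A [feature_spec()].
#' @return Character vector: question features first, then the 11 global
#'   features.
#' @export
feature_names <- function(spec) {
  c(spec$question_pool, GLOBAL_FEATURES)
}

# Cleaned, tokenized participant turns ("comments"); empty comments dropped
# for per-comment ratios but positions kept for timing features.
participant_comments <- function(session, rules) {
  txt <- session$turns$text[session$turns$speaker == "participant"]
  lapply(clean_utterance(txt, rules), tokenize)
}

#' Lexicon sentiment score of a text
#'
#' Mean polarity over tokens that have lexicon entries; 0 when no token
#' matches. The scorer is pluggable at the [feature_spec()] level; this
#' default makes sentiment exactly recomputable by hand.
#'
#' @param text A single cleaned string.
#' @param lexicon Named numeric vector, word -> polarity in \[-1, 1\].
#' @return Polarity in \[-1, 1\].
#' @export
#' @examples
#' sentiment_score("good bad", c(good = 1, bad = -1))
sentiment_score <- function(text, lexicon) {
  vals <- lexicon[tokenize(text)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' Match a bot utterance against the question pool
#'
#' Returns the first pool question whose cleaned form is contained in the
#' cleaned bot utterance, or `NA` if none is. A double match resolves to the
#' first question in pool order.
#'
#' @param bot_text A cleaned bot utterance.
#' @param question_pool Character vector of canonical questions.
#' @param rules Cleaning rules applied to the pool questions.
#' @return The matched question string, or `NA_character_`.
#' @export
match_question <- function(bot_text, question_pool,
                           rules = cleaning_rules()) {
  match_question_cleaned(bot_text, question_pool,
                         clean_utterance(question_pool, rules))
}

match_question_cleaned <- function(bot_text, question_pool, cleaned_pool) {
  hit <- which(vapply(cleaned_pool,
                      function(q) nzchar(q) && grepl(q, bot_text,
                                                     fixed = TRUE),
                      logical(1)))
  if (length(hit) == 0) return(NA_character_)
  question_pool[hit[1]]
}

#' Per-question answer-sentiment features
#'
#' For each question in the pool: the sentiment of the concatenation of the
#' participant turns between the bot turn asking that question and the next
#' bot turn. A question that is absent from the session — or asked but not
#' answered — contributes an exact 0 (the missing-question imputation rule).
#' If a question is asked more than once, the first occurrence is used.
#'
#' @param session An `interview_session`.
#' @param spec A [feature_spec()].
#' @return Named numeric vector, one value in \[-1, 1\] per pool question.
#' @export
answer_sentiment_features <- function(session, spec) {
  turns <- session$turns
  cleaned <- clean_utterance(turns$text, spec$rules)
  out <- stats::setNames(numeric(length(spec$question_pool)),
                         spec$question_pool)
  bot_idx <- which(turns$speaker == "bot")
  cleaned_pool <- clean_utterance(spec$question_pool, spec$rules)
  seen <- character()
  for (i in bot_idx) {
    q <- match_question_cleaned(cleaned[i], spec$question_pool,
                                cleaned_pool)
    if (is.na(q) || q %in% seen) next
    seen <- c(seen, q)
    nxt <- bot_idx[bot_idx > i]
    end <- if (length(nxt) > 0) nxt[1] else nrow(turns) + 1L
    span <- which(turns$speaker == "participant" &
                    seq_len(nrow(turns)) > i &
                    seq_len(nrow(turns)) < end)
    if (length(span) == 0) next   # asked but unanswered -> 0
    out[q] <- sentiment_score(paste(cleaned[span], collapse = " "),
                              spec$lexicon)
  }
  out
}

#' Whole-interview sentiment
#'
#' Sentiment of all participant comments in the session, by default scored
#' as one concatenated text (per-comment averaging is available through the
#' spec switch).
#'
#' @inheritParams answer_sentiment_features
#' @return Polarity in \[-1, 1\].
#' @export
avg_sentiment <- function(session, spec = feature_spec()) {
  comments <- participant_comments(session, spec$rules)
  comments <- comments[lengths(comments) > 0]
  if (length(comments) == 0) {
    abort_depscreen("session has no participant comments",
                    "depscreen_precondition_error")
  }
  if (spec$whole_interview_sentiment) {
    sentiment_score(paste(unlist(comments), collapse = " "), spec$lexicon)
  } else {
    mean(vapply(comments,
                function(t) sentiment_score(paste(t, collapse = " "),
                                            spec$lexicon),
                numeric(1)))
  }
}

#' Average response latency (seconds)
#'
#' Mean, over every bot-turn/participant-turn adjacency, of the gap between
#' the bot's stop time and the participant's start time; negative gaps
#' (overlapping speech) clamp to 0. No adjacency yields 0 with a warning.
#'
#' @param session An `interview_session`.
#' @return Seconds (>= 0).
#' @export
avg_response_time <- function(session) {
  turns <- session$turns
  n <- nrow(turns)
  if (n >= 2) {
    i <- which(turns$speaker[-n] == "bot" &
                 turns$speaker[-1] == "participant")
    if (length(i) > 0) {
      gaps <- pmax(turns$start_time[i + 1] - turns$stop_time[i], 0)
      return(mean(gaps))
    }
  }
  warning("no bot->participant adjacency; avg_response_time set to 0",
          call. = FALSE)
  0
}

#' Speech speed (words per second)
#'
#' Unweighted mean over participant turns of word count divided by turn
#' duration. Zero-duration turns are excluded.
#'
#' @param session An `interview_session`.
#' @param rules Cleaning rules used before counting words.
#' @return Words per second (>= 0).
#' @export
speech_speed <- function(session, rules = cleaning_rules()) {
  turns <- session$turns
  p <- which(turns$speaker == "participant")
  dur <- turns$stop_time[p] - turns$start_time[p]
  ok <- dur > 0
  if (!any(ok)) {
    abort_depscreen("no participant turn with positive duration",
                    "depscreen_precondition_error")
  }
  if (any(!ok)) {
    warning(sprintf("%d zero-duration participant turn(s) excluded",
                    sum(!ok)), call. = FALSE)
  }
  words <- vapply(clean_utterance(turns$text[p][ok], rules),
                  function(s) length(tokenize(s)), integer(1),
                  USE.NAMES = FALSE)
  mean(words / dur[ok])
}

#' Mean per-comment token ratio
#'
#' Shared engine for the lexical-frequency features: for each non-empty
#' participant comment, the fraction of tokens satisfying `predicate`,
#' averaged over comments with equal weight (not pooled).
#'
#' @param session An `interview_session`.
#' @param predicate Function `tokens -> logical vector` marking the tokens
#'   counted in the numerator.
#' @param rules Cleaning rules.
#' @return Ratio in \[0, 1\].
#' @export
per_comment_ratio <- function(session, predicate,
                              rules = cleaning_rules()) {
  comments <- participant_comments(session, rules)
  comments <- comments[lengths(comments) > 0]
  if (length(comments) == 0) {
    abort_depscreen("session has no non-empty participant comments",
                    "depscreen_precondition_error")
  }
  mean(vapply(comments, function(t) sum(predicate(t)) / length(t),
              numeric(1)))
}

#' Average unique-word frequency
#'
#' Mean over comments of (number of distinct words) / (number of words).
#'
#' @inheritParams per_comment_ratio
#' @return Ratio in (0, 1].
#' @export
avg_unique_frequency <- function(session, rules = cleaning_rules()) {
  comments <- participant_comments(session, rules)
  comments <- comments[lengths(comments) > 0]
  if (length(comments) == 0) {
    abort_depscreen("session has no non-empty participant comments",
                    "depscreen_precondition_error")
  }
  mean(vapply(comments, function(t) length(unique(t)) / length(t),
              numeric(1)))
}

#' Average filler-word frequency
#'
#' Mean per-comment fraction of non-expressive filler tokens
#' ("uh", "um", "mm" by default).
#'
#' @inheritParams per_comment_ratio
#' @param filler_words Filler-word list.
#' @return Ratio in \[0, 1\].
#' @export
avg_sw_frequency <- function(session,
                             filler_words = default_filler_words(),
                             rules = cleaning_rules()) {
  per_comment_ratio(session, function(t) t %in% filler_words, rules)
}

#' Average word length in characters
#'
#' Per comment, the total number of characters in its words divided by the
#' word count (whitespace not counted), averaged over comments.
#'
#' @inheritParams per_comment_ratio
#' @return Mean characters per word (>= 1 when any token exists).
#' @export
avg_characters <- function(session, rules = cleaning_rules()) {
  comments <- participant_comments(session, rules)
  comments <- comments[lengths(comments) > 0]
  if (length(comments) == 0) {
    abort_depscreen("session has no non-empty participant comments",
                    "depscreen_precondition_error")
  }
  mean(vapply(comments, function(t) sum(nchar(t)) / length(t), numeric(1)))
}

#' Part-of-speech frequencies
#'
#' Mean per-comment fractions of nouns, verbs, adjectives and adverbs, via a
#' pluggable tagger (tests and the synthetic corpus use a deterministic
#' dictionary tagger).
#'
#' @inheritParams per_comment_ratio
#' @param tagger Tagging function, see [default_tagger()].
#' @return Named numeric vector `avg_nouns`, `avg_verbs`, `adj_freq`,
#'   `avg_adv`.
#' @export
pos_frequencies <- function(session, tagger = default_tagger(),
                            rules = cleaning_rules()) {
  roles <- c(avg_nouns = "noun", avg_verbs = "verb",
             adj_freq = "adjective", avg_adv = "adverb")
  vapply(roles, function(r) {
    per_comment_ratio(session, function(t) tagger(t) == r, rules)
  }, numeric(1))
}

#' Average first-person-word frequency
#'
#' Mean per-comment fraction of first-person-related words
#' ("i", "we", "us", ... by default).
#'
#' @inheritParams per_comment_ratio
#' @param fp_words First-person word list.
#' @return Ratio in \[0, 1\].
#' @export
fp_avg <- function(session, fp_words = default_fp_words(),
                   rules = cleaning_rules()) {
  per_comment_ratio(session, function(t) t %in% fp_words, rules)
}

#' Extract the full feature vector for one session
#'
#' Computes all features defined by the spec. A sub-feature whose
#' precondition fails (e.g. a timing feature in a session with no usable
#' turns) is set to 0 with a warning rather than aborting a corpus run.
#'
#' @param session A valid `interview_session`.
#' @param spec A [feature_spec()].
#' @return Named numeric vector over [feature_names()], with the session id
#'   in attribute `session_id`.
#' @export
extract_features <- function(session, spec = feature_spec()) {
  stopifnot(inherits(session, "interview_session"),
            inherits(spec, "feature_spec"))
  safely0 <- function(expr, name) {
    tryCatch(expr, depscreen_precondition_error = function(e) {
      warning(sprintf("feature %s set to 0 for session %s: %s", name,
                      session$session_id, conditionMessage(e)),
              call. = FALSE)
      0
    })
  }
  pos <- safely0(pos_frequencies(session, spec$tagger, spec$rules), "pos")
  if (identical(pos, 0)) {
    pos <- c(avg_nouns = 0, avg_verbs = 0, adj_freq = 0, avg_adv = 0)
  }
  vals <- c(
    answer_sentiment_features(session, spec),
    avg_sentiment = safely0(avg_sentiment(session, spec), "avg_sentiment"),
    avg_response_time = avg_response_time(session),
    speech_speed = safely0(speech_speed(session, spec$rules),
                           "speech_speed"),
    avg_unique_frequency = safely0(
      avg_unique_frequency(session, spec$rules), "avg_unique_frequency"),
    avg_sw_frequency = safely0(
      avg_sw_frequency(session, spec$filler_words, spec$rules),
      "avg_sw_frequency"),
    avg_characters = safely0(avg_characters(session, spec$rules),
                             "avg_characters"),
    pos[c("avg_nouns", "avg_verbs", "adj_freq", "avg_adv")],
    fp_avg = safely0(fp_avg(session, spec$fp_words, spec$rules), "fp_avg")
  )
  vals <- vals[feature_names(spec)]
  attr(vals, "session_id") <- session$session_id
  vals
}

#' Extract the feature matrix for a corpus
#'
#' @param sessions List of `interview_session` objects (invalid sessions
#'   should be excluded beforehand, see [validate_session()]).
#' @param spec A [feature_spec()].
#' @param labels Optional label tibble joined by participant id; adds
#'   `phq8_binary` and `phq8_score` columns.
#' @return A tibble with `session_id`, one column per feature, and label
#'   columns when given.
#' @export
extract_feature_matrix <- function(sessions, spec = feature_spec(),
                                   labels = NULL) {
  rows <- lapply(sessions, function(s) extract_features(s, spec))
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- tibble::add_column(
    out,
    session_id = vapply(sessions, function(s) s$session_id, character(1)),
    .before = 1)
  if (!is.null(labels)) {
    idx <- match(out$session_id, labels$participant_id)
    if (anyNA(idx)) {
      abort_depscreen("session without a label record",
                      "depscreen_format_error")
    }
    out$phq8_binary <- labels$phq8_binary[idx]
    out$phq8_score <- labels$phq8_score[idx]
  }
  out
}
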