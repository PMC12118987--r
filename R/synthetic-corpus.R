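# Synthetic DAIC-WOZ-style corpus generator. Emulates the statistical
# structure the feature bank measures — timed alternating bot/participant
# turns, a canonical question pool with per-session presence, bracketed
# annotation markers, a few structurally broken sessions, and
# class-conditional shifts in speech rate, response latency, negative-word
# usage and first-person usage — with exact label prevalence and full seed
# determinism. It makes no attempt at natural-language realism beyond that
# structure.

# Fixed control-class generation constants (documented in the methods
# vignette): per-comment speech rate ~ N(base_rate, rate_sd) truncated at
# 0.5 w/s; response latency ~ 0.1 s + lognormal with mean latency_base;
# word-category probabilities for the closed vocabulary.
.gen_base <- list(
  rate = 2.5,            # words/s
  latency = 1.5,         # s
  words_min = 3L,
  words_lambda = 13,     # comment length = words_min + Poisson(words_lambda)
  p_positive = 0.10,
  p_negative = 0.10,
  p_first_person = 0.12,
  p_filler = 0.08,
  markers = c("[laughter]", "[sigh]", "<breathing>", "(scrubbed entry)")
)

#' Generator configuration
#'
#' Defines the study conditions a generated corpus emulates. The defaults
#' reproduce the reference corpus shape: 188 sessions of which 56 are from
#' depressed participants, 3 structurally broken sessions without bot
#' turns, and a 19-question canonical pool where no question appears in
#' every session.
#'
#' @param n_sessions Number of sessions.
#' @param n_depressed Number of sessions with depressed label (exact).
#' @param question_pool Canonical bot questions.
#' @param question_presence_prob Probability each pool question appears in a
#'   session (default 0.9, so most but never all sessions share a question).
#' @param n_invalid_sessions Sessions emitted with zero bot turns.
#' @param marker_rate Probability a participant utterance carries one
#'   artificial annotation marker token.
#' @param effect_sizes Class-conditional shifts added for depressed
#'   participants: `speech_speed` (words/s, negative slows speech),
#'   `response_latency` (s), `neg_word_rate` and `fp_word_rate`
#'   (probability deltas for negative-sentiment and first-person words).
#' @param noise_scales Dispersions: `speech_speed` (per-comment SD of the
#'   speech rate, words/s) and `response_latency` (log-scale SD of the
#'   latency distribution).
#' @param seed Integer master seed.
#'
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(n_sessions = 188,
                       n_depressed = 56,
                       question_pool = default_question_pool(),
                       question_presence_prob = 0.9,
                       n_invalid_sessions = 3,
                       marker_rate = 0.15,
                       effect_sizes = list(speech_speed = -0.5,
                                           response_latency = 0.6,
                                           neg_word_rate = 0.06,
                                           fp_word_rate = 0.05),
                       noise_scales = list(speech_speed = 0.35,
                                           response_latency = 0.4),
                       seed = 1) {
  defaults_eff <- list(speech_speed = 0, response_latency = 0,
                       neg_word_rate = 0, fp_word_rate = 0)
  defaults_noise <- list(speech_speed = 0.35, response_latency = 0.4)
  effect_sizes <- utils::modifyList(defaults_eff, as.list(effect_sizes))
  noise_scales <- utils::modifyList(defaults_noise, as.list(noise_scales))
  ok <- is_count(n_sessions) && is_count(n_depressed) &&
    is_count(n_invalid_sessions) &&
    n_depressed <= n_sessions && n_invalid_sessions <= n_sessions &&
    is_prob(question_presence_prob) && is_prob(marker_rate) &&
    all(vapply(noise_scales, function(x) is.numeric(x) && x >= 0,
               logical(1))) &&
    is.character(question_pool) && length(question_pool) >= 1
  if (!ok) {
    abort_depscreen("invalid generator configuration",
                    "depscreen_config_error")
  }
  structure(list(n_sessions = as.integer(n_sessions),
                 n_depressed = as.integer(n_depressed),
                 question_pool = question_pool,
                 question_presence_prob = question_presence_prob,
                 n_invalid_sessions = as.integer(n_invalid_sessions),
                 marker_rate = marker_rate,
                 effect_sizes = effect_sizes,
                 noise_scales = noise_scales,
                 seed = seed),
            class = "gen_config")
}

# Class-conditional word-category probabilities. Depressed shifts raise the
# negative-sentiment and first-person rates at the expense of neutral words.
word_category_probs <- function(config, depressed) {
  b <- .gen_base
  p <- c(positive = b$p_positive,
         negative = b$p_negative +
           if (depressed) config$effect_sizes$neg_word_rate else 0,
         first_person = b$p_first_person +
           if (depressed) config$effect_sizes$fp_word_rate else 0,
         filler = b$p_filler)
  stopifnot(sum(p) < 1)
  neutral <- 1 - sum(p)
  c(p, noun = neutral * 0.4, verb = neutral * 0.3,
    adjective = neutral * 0.15, adverb = neutral * 0.15)
}

sample_words <- function(n, probs) {
  cats <- sample(names(probs), n, replace = TRUE, prob = probs)
  out <- character(n)
  for (k in unique(cats)) {
    idx <- which(cats == k)
    words <- .vocab[[k]]
    out[idx] <- words[sample.int(length(words), length(idx),
                                 replace = TRUE)]
  }
  out
}

# Decorate a planted word sequence into a raw utterance: capitalised first
# word, trailing period, and (with probability marker_rate) one bracketed
# marker token at a random position. Cleaning recovers exactly the planted
# words.
decorate_utterance <- function(words, marker_rate) {
  if (stats::runif(1) < marker_rate) {
    marker <- .gen_base$markers[sample.int(length(.gen_base$markers), 1)]
    at <- sample.int(length(words) + 1L, 1) - 1L
    words <- append(words, marker, after = at)
  }
  words[1] <- paste0(toupper(substr(words[1], 1, 1)),
                     substr(words[1], 2, nchar(words[1])))
  paste0(paste(words, collapse = " "), ".")
}

generate_session <- function(config, index, depressed, invalid) {
  set.seed(derive_seed(config$seed, index))
  b <- .gen_base
  probs <- word_category_probs(config, depressed)
  rate_mu <- b$rate + if (depressed) config$effect_sizes$speech_speed else 0
  lat_mu <- max(b$latency +
                  if (depressed) config$effect_sizes$response_latency else 0,
                0.15)
  lat_sdlog <- config$noise_scales$response_latency
  rate_sd <- config$noise_scales$speech_speed

  questions <- character()
  latencies <- numeric()
  if (invalid) {
    # structurally broken: participant speech only, no bot turns
    m <- 2L + stats::rpois(1, 1)
    n_answers <- integer(0)
  } else {
    present <- stats::runif(length(config$question_pool)) <
      config$question_presence_prob
    if (!any(present)) present[sample.int(length(present), 1)] <- TRUE
    questions <- config$question_pool[present]
    n_answers <- 1L + (stats::runif(length(questions)) < 0.3)
    m <- sum(n_answers)
  }

  # all participant comments batched: word counts, words, speech rates
  n_words <- b$words_min + stats::rpois(m, b$words_lambda)
  words_by_comment <- split(sample_words(sum(n_words), probs),
                            rep.int(seq_len(m), n_words))
  rates <- pmax(0.5, stats::rnorm(m, rate_mu, rate_sd))
  texts <- vapply(seq_len(m), function(i) {
    decorate_utterance(words_by_comment[[i]], config$marker_rate)
  }, character(1))

  start <- numeric(); stop_ <- numeric(); speaker <- character()
  utter <- character()
  t <- round(stats::runif(1, 2, 8), 4)
  ci <- 0L
  emit_participant <- function() {
    ci <<- ci + 1L
    stop_t <- round(t + n_words[ci] / rates[ci], 4)
    start[length(start) + 1L] <<- round(t, 4)
    stop_[length(stop_) + 1L] <<- stop_t
    speaker[length(speaker) + 1L] <<- "participant"
    utter[length(utter) + 1L] <<- texts[ci]
    t <<- stop_t + round(stats::runif(1, 0.3, 1.2), 4)
  }

  if (invalid) {
    for (k in seq_len(m)) emit_participant()
  } else {
    for (qi in seq_along(questions)) {
      bot_dur <- stats::runif(1, 1.5, 3.5)
      prefix <- if (stats::runif(1) < 0.3) "So, " else ""
      start[length(start) + 1L] <- round(t, 4)
      stop_[length(stop_) + 1L] <- round(t + bot_dur, 4)
      speaker[length(speaker) + 1L] <- "bot"
      utter[length(utter) + 1L] <- paste0(prefix, questions[qi], "?")
      t <- round(t + bot_dur, 4)
      # shifted log-normal response latency with target mean lat_mu
      lat <- 0.1 + stats::rlnorm(1, log(lat_mu - 0.1) - lat_sdlog^2 / 2,
                                 lat_sdlog)
      latencies <- c(latencies, lat)
      t <- t + lat
      for (k in seq_len(n_answers[qi])) emit_participant()
      t <- t + stats::runif(1, 0.2, 1)
    }
  }
  s <- new_session(as.character(300 + index),
                   data.frame(start_time = start, stop_time = stop_,
                              speaker = speaker, text = utter,
                              stringsAsFactors = FALSE))
  s$planted <- list(depressed = depressed, questions = questions,
                    word_counts = n_words, rates = rates,
                    latencies = latencies)
  s
}

#' Generate a labelled synthetic corpus
#'
#' Produces sessions with alternating timed bot/participant turns, exactly
#' `n_depressed` depressed labels, exactly `n_invalid_sessions` sessions
#' without bot turns, and class-conditional shifts per the configuration.
#' Fully deterministic: identical configuration (including seed) yields an
#' identical corpus; each session uses a substream derived from the master
#' seed and the session index, independent of generation order.
#'
#' @param config A [gen_config()].
#'
#' @return An object of class `corpus_bundle`: list with `sessions` (each
#'   carrying its `planted` ground truth), `labels` tibble and
#'   `ground_truth` (the configuration).
#' @export
generate_corpus <- function(config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  n <- config$n_sessions
  assign_seed <- derive_seed(config$seed, 0)
  assignments <- with_seed(assign_seed, {
    list(depressed = sample.int(n, config$n_depressed),
         invalid = sample.int(n, config$n_invalid_sessions),
         scores_dep = sample(11:24, n, replace = TRUE),
         scores_ctl = sample(0:10, n, replace = TRUE),
         gender = sample(0:1, n, replace = TRUE))
  })
  depressed <- seq_len(n) %in% assignments$depressed
  invalid <- seq_len(n) %in% assignments$invalid
  sessions <- lapply(seq_len(n), function(i) {
    generate_session(config, i, depressed[i], invalid[i])
  })
  labels <- tibble::tibble(
    participant_id = vapply(sessions, function(s) s$session_id,
                            character(1)),
    phq8_binary = as.integer(depressed),
    phq8_score = ifelse(depressed, assignments$scores_dep,
                        assignments$scores_ctl),
    gender = assignments$gender
  )
  structure(list(sessions = sessions, labels = labels,
                 ground_truth = config),
            class = "corpus_bundle")
}

#' @export
print.corpus_bundle <- function(x, ...) {
  cat(sprintf(
    "<corpus_bundle: %d sessions (%d depressed, %d invalid), seed %s>\n",
    length(x$sessions), sum(x$labels$phq8_binary),
    x$ground_truth$n_invalid_sessions, format(x$ground_truth$seed)))
  invisible(x)
}

#' Write a corpus to disk
#'
#' One tab-separated transcript per session (`<id>_transcript.tsv`), the
#' label table (`labels.csv`) and a JSON manifest (file list plus
#' configuration echo). [read_corpus()] round-trips the bundle exactly.
#'
#' @param bundle A `corpus_bundle`.
#' @param directory Output directory (created if needed).
#'
#' @return Invisibly, the manifest as a list.
#' @export
write_corpus <- function(bundle, directory) {
  stopifnot(inherits(bundle, "corpus_bundle"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    abort_depscreen(sprintf("cannot create directory %s", directory),
                    "depscreen_io_error")
  }
  files <- character()
  for (s in bundle$sessions) {
    fname <- paste0(s$session_id, "_transcript.tsv")
    turns <- s$turns
    out <- data.frame(
      start_time = sprintf("%.4f", turns$start_time),
      stop_time = sprintf("%.4f", turns$stop_time),
      speaker = ifelse(turns$speaker == "bot", "Ellie", "Participant"),
      value = turns$text, stringsAsFactors = FALSE)
    utils::write.table(out, file.path(directory, fname), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, fname)
  }
  lab <- data.frame(Participant_ID = bundle$labels$participant_id,
                    PHQ8_Binary = bundle$labels$phq8_binary,
                    PHQ8_Score = bundle$labels$phq8_score,
                    Gender = bundle$labels$gender)
  utils::write.table(lab, file.path(directory, "labels.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  config <- bundle$ground_truth
  manifest <- list(transcripts = files, labels = "labels.csv",
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
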