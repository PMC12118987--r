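# Deterministic fixtures shared across the suite.

toy_lexicon <- c(good = 1, bad = -1, happy = 1, sad = -1)

toy_tagger <- function(tokens) {
  dict <- c(dogs = "noun", cat = "noun", bark = "verb", saw = "verb",
            loudly = "adverb", red = "adjective")
  roles <- unname(dict[tokens])
  roles[is.na(roles)] <- "other"
  roles
}

# A session built from explicit turns; times default to a clean alternating
# timeline if not given.
make_session <- function(speakers, texts, start = NULL, stop = NULL,
                         id = "s1") {
  n <- length(speakers)
  if (is.null(start)) start <- seq(0, by = 10, length.out = n)
  if (is.null(stop)) stop <- start + 4
  new_session(id, data.frame(start_time = start, stop_time = stop,
                             speaker = speakers, text = texts,
                             stringsAsFactors = FALSE))
}

# Single-participant-comment session with controllable timing.
comment_session <- function(texts, durations = rep(4, length(texts))) {
  n <- length(texts)
  start <- cumsum(c(0, durations[-n] + 2))
  make_session(rep("participant", n), texts, start, start + durations)
}

small_corpus <- function(seed = 1, n = 30, n_dep = 10, n_invalid = 2,
                         effect_sizes = list()) {
  generate_corpus(gen_config(n_sessions = n, n_depressed = n_dep,
                             n_invalid_sessions = n_invalid,
                             effect_sizes = effect_sizes, seed = seed))
}

valid_mask <- function(bundle) {
  vapply(bundle$sessions, function(s) validate_session(s)$valid,
         logical(1))
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent per-comment recount used as oracle for the ratio features:
# deliberately re-implemented with different primitives than the package
# (regmatches word scan instead of the package tokenizer).
oracle_comment_ratio <- function(session, rules, numerator_fun) {
  txt <- session$turns$text[session$turns$speaker == "participant"]
  vals <- c()
  for (s in clean_utterance(txt, rules)) {
    words <- regmatches(s, gregexpr("\\S+", s))[[1]]
    if (length(words) == 0) next
    vals <- c(vals, numerator_fun(words) / length(words))
  }
  mean(vals)
}
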