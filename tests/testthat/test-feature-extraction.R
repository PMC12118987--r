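toy_spec <- function(...) {
  feature_spec(question_pool = c("what's your dream job",
                                 "do you consider yourself an introvert"),
               lexicon = toy_lexicon, tagger = toy_tagger,
               filler_words = c("um", "uh", "mm"),
               fp_words = c("i", "we", "us"), ...)
}

test_that("sentiment_score is the mean lexicon polarity of matched tokens", {
  expect_equal(sentiment_score("good bad", toy_lexicon), 0)
  expect_equal(sentiment_score("good good", toy_lexicon), 1)
  expect_equal(sentiment_score("nothing matches here", toy_lexicon), 0)
  # independent recount on random token strings
  set.seed(31)
  vocab <- c(names(toy_lexicon), "the", "it", "go")
  for (i in 1:20) {
    toks <- sample(vocab, sample(1:12, 1), replace = TRUE)
    hand <- toy_lexicon[toks[toks %in% names(toy_lexicon)]]
    expected <- if (length(hand) == 0) 0 else sum(hand) / length(hand)
    expect_equal(sentiment_score(paste(toks, collapse = " "), toy_lexicon),
                 expected)
  }
})

test_that("match_question finds pool questions by containment", {
  pool <- default_question_pool()
  expect_identical(match_question("so what's your dream job", pool),
                   "what's your dream job")
  expect_identical(match_question("how are you today", pool[1:3]),
                   NA_character_)
  # first-in-pool-order tie break
  expect_identical(match_question("a b", c("b", "a b")), "b")
})

test_that("matched questions equal the generator's planted sets", {
  bundle <- small_corpus(seed = 21, n = 12, n_dep = 4, n_invalid = 0)
  rules <- cleaning_rules()
  pool <- bundle$ground_truth$question_pool
  for (s in bundle$sessions) {
    bot_txt <- clean_utterance(
      s$turns$text[s$turns$speaker == "bot"], rules)
    matched <- vapply(bot_txt, match_question, character(1),
                      question_pool = pool, USE.NAMES = FALSE)
    expect_identical(matched, s$planted$questions)
  }
})

test_that("answer sentiment features impute 0 for absent questions", {
  spec <- toy_spec()
  s <- make_session(c("bot", "participant"),
                    c("what's your dream job?", "good"))
  vals <- answer_sentiment_features(s, spec)
  expect_equal(unname(vals["what's your dream job"]), 1)
  expect_equal(unname(vals["do you consider yourself an introvert"]), 0)
  # asked but unanswered -> 0
  s2 <- make_session(c("bot", "bot", "participant"),
                     c("what's your dream job?",
                       "do you consider yourself an introvert?", "bad"))
  vals2 <- answer_sentiment_features(s2, spec)
  expect_equal(unname(vals2["what's your dream job"]), 0)
  expect_equal(unname(vals2["do you consider yourself an introvert"]), -1)
})

test_that("answer span covers participant turns until the next bot turn", {
  spec <- toy_spec()
  s <- make_session(c("bot", "participant", "participant", "bot",
                      "participant"),
                    c("what's your dream job?", "good good", "bad",
                      "do you consider yourself an introvert?", "sad"))
  vals <- answer_sentiment_features(s, spec)
  # concatenation "good good bad" -> (1+1-1)/3
  expect_equal(unname(vals["what's your dream job"]), 1 / 3)
  expect_equal(unname(vals["do you consider yourself an introvert"]), -1)
})

test_that("avg_sentiment scores the whole interview by default", {
  spec <- toy_spec()
  s <- make_session(c("bot", "participant", "participant"),
                    c("q?", "good good good", "bad"))
  expect_equal(avg_sentiment(s, spec), (3 - 1) / 4)
  per_comment <- toy_spec(whole_interview_sentiment = FALSE)
  expect_equal(avg_sentiment(s, per_comment), (1 + (-1)) / 2)
  one <- make_session(c("bot", "participant"), c("q?", "good bad good"))
  expect_equal(avg_sentiment(one, spec), 1 / 3)
  neutral <- make_session(c("bot", "participant"), c("q?", "plain words"))
  expect_equal(avg_sentiment(neutral, spec), 0)
})

test_that("avg_response_time averages clamped bot->participant gaps", {
  s <- make_session(c("bot", "participant"), c("q?", "a"),
                    start = c(5, 12.5), stop = c(10, 14))
  expect_equal(avg_response_time(s), 2.5)
  s2 <- make_session(c("bot", "participant", "bot", "participant"),
                     c("q?", "a", "q2?", "b"),
                     start = c(0, 3, 10, 15), stop = c(2, 5, 12, 17))
  expect_equal(avg_response_time(s2), 2)  # gaps 1.0 and 3.0
  # overlap clamps to zero
  s3 <- make_session(c("bot", "participant"), c("q?", "a"),
                     start = c(0, 1), stop = c(2, 4))
  expect_equal(avg_response_time(s3), 0)
  expect_warning(
    expect_equal(avg_response_time(
      make_session("participant", "a")), 0),
    "adjacency")
})

test_that("speech_speed is the unweighted mean of per-comment rates", {
  s <- make_session(c("bot", "participant"),
                    c("q?", paste(rep("word", 12), collapse = " ")),
                    start = c(0, 5), stop = c(2, 11))
  expect_equal(speech_speed(s), 2)
  s2 <- make_session(c("participant", "participant"),
                     c(paste(rep("w", 8), collapse = " "),
                       paste(rep("w", 16), collapse = " ")),
                     start = c(0, 10), stop = c(4, 14))
  expect_equal(speech_speed(s2), 3)  # rates 2.0 and 4.0
})

test_that("per-comment ratio features match their closed forms", {
  expect_equal(avg_unique_frequency(comment_session("the cat saw the cat")),
               0.6)
  expect_equal(avg_unique_frequency(comment_session("all distinct words")),
               1)
  expect_equal(avg_sw_frequency(comment_session("um i think uh maybe"),
                                c("um", "uh", "mm")), 0.4)
  expect_equal(avg_sw_frequency(comment_session("no fillers here"),
                                c("um", "uh", "mm")), 0)
  expect_equal(avg_characters(comment_session("hello world")), 5)
  expect_equal(avg_characters(comment_session("a b c")), 1)
  expect_equal(fp_avg(comment_session("i think we should go"),
                      c("i", "we", "us")), 0.4)
  expect_equal(fp_avg(comment_session("nobody here"), c("i", "we")), 0)
})

test_that("pos_frequencies uses the pluggable tagger", {
  vals <- pos_frequencies(comment_session("dogs bark loudly"), toy_tagger)
  expect_equal(unname(vals["avg_nouns"]), 1 / 3)
  expect_equal(unname(vals["avg_verbs"]), 1 / 3)
  expect_equal(unname(vals["avg_adv"]), 1 / 3)
  expect_equal(unname(vals["adj_freq"]), 0)
  none <- pos_frequencies(comment_session("zz yy xx"), toy_tagger)
  expect_equal(unname(none), c(0, 0, 0, 0))
})

test_that("ratio features agree with an independent recount", {
  bundle <- small_corpus(seed = 17, n = 8, n_dep = 3, n_invalid = 0)
  rules <- cleaning_rules()
  tagger <- default_tagger()
  for (s in bundle$sessions[1:4]) {
    expect_equal(avg_unique_frequency(s),
                 oracle_comment_ratio(s, rules,
                                      function(w) length(unique(w))))
    expect_equal(avg_sw_frequency(s),
                 oracle_comment_ratio(s, rules, function(w)
                   sum(w %in% default_filler_words())))
    expect_equal(avg_characters(s),
                 oracle_comment_ratio(s, rules, function(w)
                   sum(nchar(w))))
    expect_equal(fp_avg(s),
                 oracle_comment_ratio(s, rules, function(w)
                   sum(w %in% default_fp_words())))
    expect_equal(unname(pos_frequencies(s)["avg_nouns"]),
                 oracle_comment_ratio(s, rules, function(w)
                   sum(tagger(w) == "noun")))
  }
})

test_that("extract_features returns all 30 named values", {
  spec <- feature_spec()
  s <- make_session(c("bot", "participant"),
                    c("how are you doing today?", "Fine, thanks. I go."))
  vals <- extract_features(s, spec)
  expect_length(vals, 30)
  expect_identical(names(vals), feature_names(spec))
  absent <- setdiff(spec$question_pool, "how are you doing today")
  expect_true(all(vals[absent] == 0))
})

test_that("feature matrix round-trips through CSV", {
  bundle <- small_corpus(seed = 13, n = 10, n_dep = 3, n_invalid = 1)
  keep <- valid_mask(bundle)
  fm <- extract_feature_matrix(bundle$sessions[keep], feature_spec(),
                               bundle$labels)
  expect_equal(nrow(fm), sum(keep))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(fm, path, row.names = FALSE)
  back <- utils::read.csv(path, check.names = FALSE,
                          colClasses = c(session_id = "character"))
  expect_equal(as.data.frame(fm), back, tolerance = 1e-12)
})

test_that("feature ranges hold on every session of a seeded corpus", {
  bundle <- small_corpus(seed = 77, n = 25, n_dep = 9, n_invalid = 0,
                         effect_sizes = list(speech_speed = -0.6,
                                             response_latency = 0.8,
                                             neg_word_rate = 0.08,
                                             fp_word_rate = 0.06))
  spec <- feature_spec()
  fm <- extract_feature_matrix(bundle$sessions, spec)
  ratios <- c("avg_unique_frequency", "avg_sw_frequency", "avg_nouns",
              "avg_verbs", "adj_freq", "avg_adv", "fp_avg")
  for (f in ratios) {
    expect_true(all(fm[[f]] >= 0 & fm[[f]] <= 1))
  }
  sentiments <- c(spec$question_pool, "avg_sentiment")
  for (f in sentiments) {
    expect_true(all(fm[[f]] >= -1 & fm[[f]] <= 1))
  }
  expect_true(all(fm$speech_speed >= 0))
  expect_true(all(fm$avg_response_time >= 0))
  expect_true(all(fm$avg_characters >= 1))
})

test_that("per-comment averages are invariant to comment order and duplication", {
  texts <- c("good good bad", "um i think", "the cat saw the cat")
  durs <- c(3, 2, 5)
  base <- comment_session(texts, durs)
  perm <- comment_session(texts[c(3, 1, 2)], durs[c(3, 1, 2)])
  dup <- comment_session(rep(texts, 2), rep(durs, 2))
  feats <- function(s) c(
    avg_unique_frequency(s), avg_sw_frequency(s), avg_characters(s),
    fp_avg(s), speech_speed(s),
    pos_frequencies(s, toy_tagger))
  expect_equal(feats(perm), feats(base))
  expect_equal(feats(dup), feats(base))
})

test_that("timing features are invariant to a global timestamp shift", {
  s <- make_session(c("bot", "participant", "bot", "participant"),
                    c("q?", "some words here", "q2?", "more words"),
                    start = c(0, 3, 10, 14.5), stop = c(2, 6, 13, 16))
  shift <- s
  shift$turns$start_time <- shift$turns$start_time + 1000
  shift$turns$stop_time <- shift$turns$stop_time + 1000
  expect_equal(avg_response_time(shift), avg_response_time(s))
  expect_equal(speech_speed(shift), speech_speed(s))
})
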