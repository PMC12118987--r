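# Reading and validating transcripts and PHQ-8 label tables, and the
# train/test split. Transcript dialect: tab-separated turn records with
# header `start_time  stop_time  speaker  value`, times in seconds. Label
# dialect: CSV with header `Participant_ID,PHQ8_Binary,PHQ8_Score,Gender`.

#' Construct an interview session
#'
#' @param session_id Session identifier (coerced to character).
#' @param turns Data frame with columns `start_time`, `stop_time`
#'   (seconds, `stop_time >= start_time`), `speaker` (`"bot"` or
#'   `"participant"`), `text`. Turns are kept sorted by `start_time`
#'   (ties broken by input order).
#'
#' @return An object of class `interview_session`.
#' @export
new_session <- function(session_id, turns) {
  stopifnot(is.data.frame(turns),
            all(c("start_time", "stop_time", "speaker", "text") %in%
                  names(turns)))
  if (nrow(turns) > 0) {
    if (any(turns$stop_time < turns$start_time)) {
      abort_depscreen("turn stop_time precedes start_time",
                      "depscreen_record_error")
    }
    if (!all(turns$speaker %in% c("bot", "participant"))) {
      abort_depscreen("speaker must be 'bot' or 'participant'",
                      "depscreen_record_error")
    }
    turns <- turns[order(turns$start_time), , drop = FALSE]
    rownames(turns) <- NULL
  }
  structure(list(session_id = as.character(session_id),
                 turns = turns[, c("start_time", "stop_time", "speaker",
                                   "text")]),
            class = "interview_session")
}

#' @export
print.interview_session <- function(x, ...) {
  cat(sprintf("<interview_session %s: %d turns (%d bot, %d participant)>\n",
              x$session_id, nrow(x$turns),
              sum(x$turns$speaker == "bot"),
              sum(x$turns$speaker == "participant")))
  invisible(x)
}

#' Read a transcript file
#'
#' Parses a tab-separated transcript into an [new_session()] object. Speaker
#' strings are mapped to the two roles through a case-insensitive alias
#' table; the default maps the interviewer agent name "Ellie" to the bot
#' role. Turns are re-sorted by start time.
#'
#' @param path Path to a TSV file with header
#'   `start_time`, `stop_time`, `speaker`, `value`.
#' @param speaker_aliases Named character vector mapping lower-cased speaker
#'   strings to roles `"bot"`/`"participant"`.
#' @param session_id Session identifier; defaults to the file name stripped
#'   of a `_transcript`/`_TRANSCRIPT` suffix and extension.
#'
#' @return An `interview_session`.
#' @export
read_transcript <- function(path,
                            speaker_aliases = c(ellie = "bot",
                                                participant = "participant"),
                            session_id = NULL) {
  if (!file.exists(path)) {
    abort_depscreen(sprintf("transcript file not found: %s", path),
                    "depscreen_io_error")
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           check.names = TRUE)
  required <- c("start_time", "stop_time", "speaker", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_depscreen(sprintf("transcript %s missing column(s): %s", path,
                            paste(missing, collapse = ", ")),
                    "depscreen_format_error")
  }
  start <- suppressWarnings(as.numeric(raw$start_time))
  stop_ <- suppressWarnings(as.numeric(raw$stop_time))
  bad <- which(is.na(start) | is.na(stop_))
  if (length(bad) > 0) {
    abort_depscreen(sprintf("non-numeric time in %s at line %d", path,
                            bad[1] + 1L),  # +1 for the header row
                    "depscreen_record_error")
  }
  role <- unname(speaker_aliases[tolower(trimws(raw$speaker))])
  unknown <- which(is.na(role))
  if (length(unknown) > 0) {
    abort_depscreen(sprintf("unknown speaker '%s' in %s at line %d",
                            raw$speaker[unknown[1]], path,
                            unknown[1] + 1L),
                    "depscreen_record_error")
  }
  if (is.null(session_id)) {
    session_id <- sub("_transcript$", "",
                      sub("\\.[^.]*$", "", basename(path)),
                      ignore.case = TRUE)
  }
  new_session(session_id,
              data.frame(start_time = start, stop_time = stop_,
                         speaker = role, text = raw$value,
                         stringsAsFactors = FALSE))
}

#' Read a PHQ-8 label table
#'
#' Reads the CSV label table and validates each record against the binary
#' threshold rule: a PHQ-8 total above `threshold` corresponds to the
#' depressed binary label 1. Gender is carried through but never enters any
#' model.
#'
#' @param path CSV file with header
#'   `Participant_ID,PHQ8_Binary,PHQ8_Score,Gender`.
#' @param threshold Score threshold for the binary rule (`score > threshold`
#'   implies label 1); default 10.
#' @param strict If `TRUE`, a binary/score inconsistency is an error instead
#'   of a warning.
#'
#' @return A tibble with columns `participant_id`, `phq8_binary`,
#'   `phq8_score`, `gender`.
#' @export
read_labels <- function(path, threshold = 10, strict = FALSE) {
  if (!file.exists(path)) {
    abort_depscreen(sprintf("label file not found: %s", path),
                    "depscreen_io_error")
  }
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = TRUE)
  required <- c("Participant_ID", "PHQ8_Binary", "PHQ8_Score", "Gender")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_depscreen(sprintf("label table missing column(s): %s",
                            paste(missing, collapse = ", ")),
                    "depscreen_format_error")
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(participant_id = character(),
                          phq8_binary = integer(),
                          phq8_score = integer(),
                          gender = integer()))
  }
  ids <- trimws(raw$Participant_ID)
  if (anyDuplicated(ids)) {
    abort_depscreen(sprintf("duplicate participant_id: %s",
                            ids[duplicated(ids)][1]),
                    "depscreen_format_error")
  }
  labels <- tibble::tibble(
    participant_id = ids,
    phq8_binary = as.integer(raw$PHQ8_Binary),
    phq8_score = as.integer(raw$PHQ8_Score),
    gender = as.integer(raw$Gender)
  )
  stopifnot(all(labels$phq8_binary %in% c(0L, 1L)),
            all(labels$phq8_score >= 0 & labels$phq8_score <= 24))
  implied <- as.integer(labels$phq8_score > threshold)
  off <- which(implied != labels$phq8_binary)
  if (length(off) > 0) {
    msg <- sprintf(
      "%d record(s) violate the 'score > %d <=> binary 1' rule (first: %s)",
      length(off), threshold, labels$participant_id[off[1]])
    if (strict) abort_depscreen(msg, "depscreen_format_error")
    warning(msg, call. = FALSE)
  }
  labels
}

#' Validate a session's structure
#'
#' A session is invalid if it contains no bot turns: most features depend on
#' questions asked by the interviewer agent, so participant-only transcripts
#' are excluded from analysis. Additional checks can be enabled.
#'
#' @param session An `interview_session`.
#' @param checks Which structural checks to apply: `"bot"` (no bot turns =>
#'   invalid; always sensible), optionally `"participant"` (no participant
#'   turns) and `"nonempty"` (no turns at all).
#'
#' @return A list with `valid` (logical) and `reasons` (character).
#' @export
validate_session <- function(session, checks = "bot") {
  stopifnot(inherits(session, "interview_session"))
  checks <- match.arg(checks, c("bot", "participant", "nonempty"),
                      several.ok = TRUE)
  reasons <- character()
  if ("nonempty" %in% checks && nrow(session$turns) == 0) {
    reasons <- c(reasons, "no turns")
  }
  if ("bot" %in% checks && sum(session$turns$speaker == "bot") == 0) {
    reasons <- c(reasons, "no bot turns")
  }
  if ("participant" %in% checks &&
      sum(session$turns$speaker == "participant") == 0) {
    reasons <- c(reasons, "no participant turns")
  }
  list(valid = length(reasons) == 0, reasons = reasons)
}

#' Split a corpus into training and testing sets
#'
#' Structurally invalid sessions (per [validate_session()]) are removed
#' first; the retained sessions are then partitioned by a seeded uniform
#' permutation, with `round(train_fraction * n)` sessions in the training
#' set. With 185 retained sessions and the default fraction 0.8 this yields
#' the 148/37 split.
#'
#' @param sessions List of `interview_session` objects.
#' @param labels Label tibble from [read_labels()]; must cover every
#'   retained session id.
#' @param train_fraction Fraction assigned to training (strictly between 0
#'   and 1); default 0.8.
#' @param seed Integer seed controlling the permutation.
#' @param checks Validation checks passed to [validate_session()].
#'
#' @return An object of class `corpus_split`: list with `train_ids`,
#'   `test_ids`, `seed`.
#' @export
split_corpus <- function(sessions, labels, train_fraction = 0.8, seed = 1,
                         checks = "bot") {
  stopifnot(is.list(sessions),
            is.numeric(train_fraction), length(train_fraction) == 1L,
            train_fraction > 0, train_fraction < 1)
  ids <- vapply(sessions, function(s) s$session_id, character(1))
  keep <- vapply(sessions, function(s) validate_session(s, checks)$valid,
                 logical(1))
  retained <- ids[keep]
  unlabeled <- setdiff(retained, labels$participant_id)
  if (length(unlabeled) > 0) {
    abort_depscreen(sprintf("session(s) without a label record: %s",
                            paste(utils::head(unlabeled, 3),
                                  collapse = ", ")),
                    "depscreen_format_error")
  }
  n <- length(retained)
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n - n_train < 1) {
    abort_depscreen("split would leave an empty training or testing set",
                    "depscreen_config_error")
  }
  perm <- with_seed(seed, sample(retained, n))
  structure(list(train_ids = sort(perm[seq_len(n_train)]),
                 test_ids = sort(perm[(n_train + 1):n]),
                 seed = seed),
            class = "corpus_split")
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf("<corpus_split: %d train / %d test (seed %s)>\n",
              length(x$train_ids), length(x$test_ids), format(x$seed)))
  invisible(x)
}

#' Read a corpus directory
#'
#' Reads every `*_transcript.tsv` file plus `labels.csv` from a directory
#' written by [write_corpus()] (or laid out in the same dialect).
#'
#' @param directory Corpus directory.
#' @param ... Passed to [read_transcript()] and [read_labels()].
#'
#' @return List with `sessions` (list of `interview_session`) and `labels`.
#' @export
read_corpus <- function(directory, ...) {
  files <- sort(list.files(directory, pattern = "_transcript\\.tsv$",
                           full.names = TRUE, ignore.case = TRUE))
  sessions <- lapply(files, read_transcript)
  labels <- read_labels(file.path(directory, "labels.csv"))
  list(sessions = sessions, labels = labels)
}
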