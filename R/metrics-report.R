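# Imbalance-aware classification metrics in the layout of a standard
# classification report (per-class precision/recall/F1/support, accuracy,
# macro and support-weighted averages), the F1-constrained selection rule,
# and report rendering. All averages are computed from unrounded per-class
# values; 2-decimal rounding is display-only.

#' Confusion matrix for binary labels
#'
#' @param y_true,y_pred Equal-length vectors with values in \{0, 1\}.
#' @return 2x2 integer matrix, rows = true class, columns = predicted class,
#'   dimnames `true`/`pred` in class order 0, 1.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort_depscreen("y_true and y_pred lengths differ",
                    "depscreen_config_error")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    abort_depscreen("labels must be 0 or 1", "depscreen_config_error")
  }
  m <- table(factor(y_true, levels = c(0, 1)),
             factor(y_pred, levels = c(0, 1)))
  m <- matrix(as.integer(m), 2, 2,
              dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  m
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2pr/(p+r)`, defined as 0 when both are 0. Vectorized.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_from_pr <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Summarize a confusion matrix
#'
#' Per-class precision, recall, F1 and support, accuracy, and macro
#' (unweighted) and weighted (support-weighted) averages. A class absent
#' from predictions or truth gets precision/recall/F1 of 0.
#'
#' @param cm 2x2 confusion matrix from [confusion()] (rows = true class).
#' @return An object of class `metrics_table`.
#' @export
summarize_confusion <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 2), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) {
    abort_depscreen("empty confusion matrix", "depscreen_config_error")
  }
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted == 0, 0, diag(cm) / predicted)
  recall <- ifelse(support == 0, 0, diag(cm) / support)
  f1 <- f1_from_pr(precision, recall)
  w <- support / total
  structure(list(
    per_class = tibble::tibble(class = c("0", "1"),
                               precision = unname(precision),
                               recall = unname(recall),
                               f1 = unname(f1),
                               support = unname(as.integer(support))),
    accuracy = sum(diag(cm)) / total,
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    total = as.integer(total)
  ), class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f", v)
  cat(sprintf("%-14s%10s%10s%10s%10s\n", "Class", "Precision", "Recall",
              "F1-Score", "Support"))
  for (i in 1:2) {
    cat(sprintf("%-14s%10s%10s%10s%10d\n", x$per_class$class[i],
                fmt(x$per_class$precision[i]), fmt(x$per_class$recall[i]),
                fmt(x$per_class$f1[i]), x$per_class$support[i]))
  }
  cat(sprintf("%-14s%10s%10s%10s%10d\n", "Accuracy", "", "",
              fmt(x$accuracy), x$total))
  cat(sprintf("%-14s%10s%10s%10s%10d\n", "Macro Avg", fmt(x$macro[1]),
              fmt(x$macro[2]), fmt(x$macro[3]), x$total))
  cat(sprintf("%-14s%10s%10s%10s%10d\n", "Weighted Avg", fmt(x$weighted[1]),
              fmt(x$weighted[2]), fmt(x$weighted[3]), x$total))
  invisible(x)
}

#' Model-selection policy
#'
#' Accuracy-first selection subject to a minority-class F1 constraint,
#' guarding against degenerate majority-class predictors. The constraint is
#' either a floor (minority F1 must strictly exceed `min_minority_f1`;
#' default 0) or `"argmax"` (keep only candidates attaining the best
#' minority F1). Ties in accuracy break by higher minority F1, then fewer
#' features, then lexicographic feature subset, giving a total order.
#'
#' @param min_minority_f1 Floor for the minority-class F1 (default 0, i.e.
#'   minority F1 must be strictly positive).
#' @param constraint `"floor"` or `"argmax"`.
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(min_minority_f1 = 0,
                             constraint = c("floor", "argmax")) {
  stopifnot(is.numeric(min_minority_f1), min_minority_f1 >= 0,
            min_minority_f1 <= 1)
  structure(list(min_minority_f1 = min_minority_f1,
                 constraint = match.arg(constraint)),
            class = "selection_policy")
}

rank_order <- function(results) {
  order(-results$accuracy, -results$minority_f1, results$n_features,
        results$subset, method = "radix")
}

#' Select the best model under the F1-constrained policy
#'
#' Discards candidates whose minority-class F1 fails the policy constraint,
#' then ranks survivors by accuracy (ties: minority F1, subset size,
#' lexicographic subset). If every candidate is discarded the unconstrained
#' ranking is returned with `constrained_empty = TRUE` and no winner.
#'
#' @param results Tibble of search results from [run_search()].
#' @param policy A [selection_policy()].
#' @return An object of class `model_selection`: list with `winner`
#'   (one-row tibble or `NULL`), `ranking`, `constrained_empty`, `policy`.
#' @export
select_best <- function(results, policy = selection_policy()) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) {
    abort_depscreen("no candidates to select from",
                    "depscreen_config_error")
  }
  ok <- results[!results$failed, , drop = FALSE]
  if (nrow(ok) == 0) {
    abort_depscreen("all candidates failed", "depscreen_config_error")
  }
  keep <- if (policy$constraint == "floor") {
    ok$minority_f1 > policy$min_minority_f1
  } else {
    ok$minority_f1 == max(ok$minority_f1)
  }
  survivors <- ok[keep, , drop = FALSE]
  if (nrow(survivors) == 0) {
    ranking <- ok[rank_order(ok), , drop = FALSE]
    return(structure(list(winner = NULL, ranking = ranking,
                          constrained_empty = TRUE, policy = policy),
                     class = "model_selection"))
  }
  ranking <- survivors[rank_order(survivors), , drop = FALSE]
  structure(list(winner = ranking[1, , drop = FALSE], ranking = ranking,
                 constrained_empty = FALSE, policy = policy),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  if (x$constrained_empty) {
    cat("<model_selection: no candidate met the minority-F1 constraint>\n")
  } else {
    cat(sprintf(
      "<model_selection: %s, accuracy %.2f, minority F1 %.2f,\n  features [%s]>\n",
      x$winner$family, x$winner$accuracy, x$winner$minority_f1,
      x$winner$subset))
  }
  invisible(x)
}

#' Render the final report
#'
#' Writes a machine-readable `report.json` (winner, top candidates,
#' baseline reference, policy echo) and a human-readable `ranking.csv` with
#' 2-decimal display rounding. Deterministic: regenerating from the same
#' inputs is byte-identical.
#'
#' @param results Full results tibble from [run_search()].
#' @param baseline Named list or vector of constant-class baseline
#'   accuracies (see [constant_class_baseline()]).
#' @param selection A `model_selection` from [select_best()].
#' @param directory Output directory.
#' @param top_n Number of top candidates echoed into the JSON report.
#' @return Invisibly, the paths of the written files.
#' @export
render_report <- function(results, baseline, selection, directory,
                          top_n = 5) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    abort_depscreen(sprintf("cannot create directory %s", directory),
                    "depscreen_io_error")
  }
  ranking <- selection$ranking
  top <- utils::head(ranking, top_n)
  report <- list(
    n_candidates = nrow(results),
    n_failed = sum(results$failed),
    baseline = as.list(baseline),
    policy = unclass(selection$policy),
    constrained_empty = selection$constrained_empty,
    winner = if (!selection$constrained_empty) {
      as.list(selection$winner)
    },
    top_candidates = top
  )
  json_path <- file.path(directory, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  csv_path <- file.path(directory, "ranking.csv")
  disp <- as.data.frame(ranking)
  num <- vapply(disp, is.double, logical(1))
  disp[num] <- lapply(disp[num], function(v) sprintf("%.2f", v))
  utils::write.csv(disp, csv_path, row.names = FALSE, quote = TRUE)
  invisible(c(json = json_path, csv = csv_path))
}
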