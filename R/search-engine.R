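# Exhaustive wrapper search: every k-subset of a feature pool crossed with
# every hyperparameter setting, for each of three classifier families.
# Candidates are trained on the fixed training split and evaluated on the
# held-out split only (no cross-validation); adapters receive the spec's
# seed as their randomness control, so a run is fully deterministic.

FAMILIES <- c("random_forest", "gradient_boosted_trees", "svm")

#' Feature pool for subset enumeration
#'
#' @param names Ordered feature names used for subset enumeration (no
#'   duplicates).
#' @return Character vector of class `feature_pool`.
#' @export
feature_pool <- function(names) {
  stopifnot(is.character(names), length(names) >= 1)
  if (anyDuplicated(names)) {
    abort_depscreen("duplicate names in feature pool",
                    "depscreen_config_error")
  }
  structure(names, class = "feature_pool")
}

#' Default 17-feature experimental pool
#'
#' The documented default pool for the exhaustive search: the five global
#' features recurring in published top-model feature sets
#' (`speech_speed`, `avg_characters`, `avg_nouns`, `avg_response_time`,
#' `adj_freq`), three further global features (`avg_sentiment`, `fp_avg`,
#' `avg_sw_frequency`), and the nine canonical per-question
#' answer-sentiment features.
#'
#' @return A [feature_pool()] of 17 names.
#' @export
default_feature_pool <- function() {
  feature_pool(c(
    "speech_speed", "avg_characters", "avg_nouns", "avg_response_time",
    "adj_freq", "avg_sentiment", "fp_avg", "avg_sw_frequency",
    default_question_pool()[1:9]
  ))
}

#' Estimator specification
#'
#' One classifier family with its fixed parameters, hyperparameter grid,
#' feature-subset size and seed. The fit/predict adapter is pluggable: any
#' `function(x_train, y_train, x_test, params, seed) -> 0/1 predictions`
#' can replace the built-in one.
#'
#' @param family `"random_forest"`, `"gradient_boosted_trees"` or `"svm"`.
#' @param fixed_params Named list merged into every grid setting.
#' @param grid_params Named list of value vectors; the grid is their
#'   Cartesian product.
#' @param subset_size Number of features per candidate subset.
#' @param seed Integer randomness control handed to the adapter.
#' @param fit_predict Optional adapter override.
#' @return An object of class `estimator_spec`.
#' @export
estimator_spec <- function(family = FAMILIES, fixed_params = list(),
                           grid_params = list(), subset_size = 4,
                           seed = 1, fit_predict = NULL) {
  family <- match.arg(family)
  stopifnot(is.list(fixed_params), is.list(grid_params),
            is_count(subset_size), subset_size >= 1)
  if (length(grid_params) > 0 &&
      (is.null(names(grid_params)) || any(!nzchar(names(grid_params))) ||
         any(lengths(grid_params) == 0))) {
    abort_depscreen("grid parameters must be named and non-empty",
                    "depscreen_config_error")
  }
  structure(list(family = family, fixed_params = fixed_params,
                 grid_params = grid_params,
                 subset_size = as.integer(subset_size), seed = seed,
                 fit_predict = fit_predict),
            class = "estimator_spec")
}

#' Default estimator specifications
#'
#' The three families with their documented defaults: random forest with
#' fixed parameters (`max_depth` 12, seed) and subsets of 5; gradient
#' boosted trees with `eval_metric` auc, `learning_rate` 0.01,
#' `max_depth` 12, an `n_estimators` grid of 100/300/500 and subsets of 4;
#' SVM with gamma \{1, 0.1, 0.01, 0.001\} x C \{1, 10, 100, 1000\} x
#' kernel \{rbf, linear\} and subsets of 4.
#'
#' @param seed Integer seed shared by the specs.
#' @return Named list of [estimator_spec()] objects.
#' @export
default_estimator_specs <- function(seed = 1) {
  list(
    random_forest = estimator_spec(
      "random_forest",
      fixed_params = list(n_estimators = 100, max_depth = 12),
      subset_size = 5, seed = seed),
    gradient_boosted_trees = estimator_spec(
      "gradient_boosted_trees",
      fixed_params = list(eval_metric = "auc", learning_rate = 0.01,
                          max_depth = 12),
      grid_params = list(n_estimators = c(100, 300, 500)),
      subset_size = 4, seed = seed),
    svm = estimator_spec(
      "svm",
      grid_params = list(gamma = c(1, 0.1, 0.01, 0.001),
                         C = c(1, 10, 100, 1000),
                         kernel = c("rbf", "linear")),
      subset_size = 4, seed = seed)
  )
}

#' Enumerate feature subsets
#'
#' All `choose(|pool|, k)` unordered k-subsets, each in pool order,
#' enumerated in lexicographic index order.
#'
#' @param pool A [feature_pool()] or character vector.
#' @param k Subset size, `1 <= k <= |pool|`.
#' @return List of character vectors.
#' @export
enumerate_feature_subsets <- function(pool, k) {
  pool <- as.character(pool)
  if (!is_count(k) || k < 1 || k > length(pool)) {
    abort_depscreen("subset size k out of range", "depscreen_config_error")
  }
  utils::combn(pool, k, simplify = FALSE)
}

#' Build a hyperparameter grid
#'
#' Cartesian product of the spec's grid parameters, each setting merged
#' over the fixed parameters, in deterministic order (first grid parameter
#' varies fastest). An empty grid yields the single fixed setting.
#'
#' @param spec An [estimator_spec()].
#' @return List of named parameter lists.
#' @export
build_param_grid <- function(spec) {
  stopifnot(inherits(spec, "estimator_spec"))
  if (length(spec$grid_params) == 0) {
    return(list(spec$fixed_params))
  }
  grid <- expand.grid(spec$grid_params, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    utils::modifyList(spec$fixed_params, as.list(grid[i, , drop = FALSE]))
  })
}

#' Search-space size
#'
#' @param n_subsets,n_settings Counts.
#' @return Their product.
#' @export
search_space_size <- function(n_subsets, n_settings) {
  stopifnot(is_count(n_subsets), is_count(n_settings))
  n_subsets * n_settings
}

#' Constant-class baseline accuracy
#'
#' Accuracy of the degenerate predictor assigning `class_value` to every
#' test instance: the prevalence of that class in the test labels.
#'
#' @param test_labels Vector of 0/1 test labels.
#' @param class_value The constantly predicted class (0 or 1).
#' @return Accuracy in \[0, 1\].
#' @export
constant_class_baseline <- function(test_labels, class_value) {
  stopifnot(all(test_labels %in% c(0, 1)), class_value %in% c(0, 1),
            length(test_labels) > 0)
  mean(test_labels == class_value)
}

# --- built-in estimator adapters -------------------------------------------

fit_predict_random_forest <- function(x_train, y_train, x_test, params,
                                      seed) {
  fit <- ranger::ranger(
    x = x_train, y = factor(y_train, levels = c(0, 1)),
    num.trees = params$n_estimators %||% 100,
    max.depth = params$max_depth %||% 12,
    seed = seed, num.threads = 1)
  as.integer(as.character(
    stats::predict(fit, data = x_test, num.threads = 1)$predictions))
}

fit_predict_gradient_boosted_trees <- function(x_train, y_train, x_test,
                                               params, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x_train), label = y_train)
  with_seed(seed, {
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eval_metric = params$eval_metric %||% "logloss",
                    eta = params$learning_rate %||% 0.3,
                    max_depth = params$max_depth %||% 6,
                    nthread = 1, seed = seed),
      data = dtrain,
      nrounds = params$n_estimators %||% 100,
      verbose = 0)
    as.integer(stats::predict(fit, as.matrix(x_test)) > 0.5)
  })
}

fit_predict_svm <- function(x_train, y_train, x_test, params, seed) {
  kernel <- switch(params$kernel %||% "rbf",
                   rbf = "radial", linear = "linear",
                   abort_depscreen(sprintf("unknown SVM kernel '%s'",
                                           params$kernel),
                                   "depscreen_config_error"))
  fit <- e1071::svm(x = as.matrix(x_train),
                    y = factor(y_train, levels = c(0, 1)),
                    kernel = kernel,
                    gamma = params$gamma %||% (1 / ncol(x_train)),
                    cost = params$C %||% 1, scale = FALSE)
  as.integer(as.character(stats::predict(fit, as.matrix(x_test))))
}

builtin_adapter <- function(family) {
  switch(family,
         random_forest = fit_predict_random_forest,
         gradient_boosted_trees = fit_predict_gradient_boosted_trees,
         svm = fit_predict_svm)
}

# --- the search loop --------------------------------------------------------

#' Run the exhaustive feature-subset x hyperparameter search
#'
#' For each estimator spec, trains and evaluates one candidate per
#' (feature subset x grid setting) pair on the fixed split, producing one
#' result row per candidate with its confusion matrix and derived metrics.
#' A candidate whose adapter fails is marked `failed` and the search
#' continues.
#'
#' @param features Feature matrix tibble from [extract_feature_matrix()]
#'   with a `session_id` column and the label column.
#' @param split A `corpus_split` from [split_corpus()].
#' @param pool A [feature_pool()]; must be a subset of the feature columns.
#' @param specs List of [estimator_spec()] objects (or a single spec).
#' @param label_col Name of the 0/1 label column (default `phq8_binary`).
#' @return Tibble with one row per candidate: family, params (JSON),
#'   subset, confusion counts (`n00`, `n01`, `n10`, `n11`; first digit =
#'   true class), supports, accuracy, per-class precision/recall/F1, macro
#'   and weighted F1, `minority_f1`, sizes and `failed`.
#' @export
run_search <- function(features, split, pool, specs,
                       label_col = "phq8_binary") {
  stopifnot(is.data.frame(features), inherits(split, "corpus_split"))
  if (inherits(specs, "estimator_spec")) specs <- list(specs)
  pool <- as.character(pool)
  missing_cols <- setdiff(c(pool, label_col, "session_id"),
                          colnames(features))
  if (length(missing_cols) > 0) {
    abort_depscreen(sprintf("feature matrix missing column(s): %s",
                            paste(missing_cols, collapse = ", ")),
                    "depscreen_format_error")
  }
  missing_ids <- setdiff(c(split$train_ids, split$test_ids),
                         features$session_id)
  if (length(missing_ids) > 0) {
    abort_depscreen("split ids absent from feature matrix",
                    "depscreen_format_error")
  }
  tr <- features$session_id %in% split$train_ids
  te <- features$session_id %in% split$test_ids
  y_train <- features[[label_col]][tr]
  y_test <- features[[label_col]][te]
  minority_class <- if (sum(y_test == 0) < sum(y_test == 1)) "0" else "1"

  rows <- list()
  for (spec in specs) {
    adapter <- spec$fit_predict %||% builtin_adapter(spec$family)
    subsets <- enumerate_feature_subsets(pool, spec$subset_size)
    settings <- build_param_grid(spec)
    for (subset in subsets) {
      x_train <- as.data.frame(features[tr, subset, drop = FALSE])
      x_test <- as.data.frame(features[te, subset, drop = FALSE])
      for (setting in settings) {
        pred <- tryCatch(
          adapter(x_train, y_train, x_test, setting, spec$seed),
          error = function(e) e)
        row <- list(
          family = spec$family,
          params = as.character(jsonlite::toJSON(setting,
                                                 auto_unbox = TRUE)),
          n_features = length(subset),
          subset = paste(subset, collapse = ","),
          n_train = sum(tr), n_test = sum(te))
        if (inherits(pred, "error") || length(pred) != sum(te) ||
              anyNA(pred)) {
          msg <- if (inherits(pred, "error")) conditionMessage(pred) else
            "adapter returned malformed predictions"
          warning(sprintf("candidate failed (%s, [%s]): %s", spec$family,
                          row$subset, msg), call. = FALSE)
          row <- c(row, list(
            n00 = NA_integer_, n01 = NA_integer_, n10 = NA_integer_,
            n11 = NA_integer_, support_0 = NA_integer_,
            support_1 = NA_integer_, accuracy = NA_real_,
            precision_0 = NA_real_, recall_0 = NA_real_, f1_0 = NA_real_,
            precision_1 = NA_real_, recall_1 = NA_real_, f1_1 = NA_real_,
            macro_f1 = NA_real_, weighted_f1 = NA_real_,
            minority_f1 = NA_real_, failed = TRUE))
        } else {
          cm <- confusion(y_test, pred)
          mt <- summarize_confusion(cm)
          f1s <- stats::setNames(mt$per_class$f1, mt$per_class$class)
          row <- c(row, list(
            n00 = cm[1, 1], n01 = cm[1, 2], n10 = cm[2, 1], n11 = cm[2, 2],
            support_0 = mt$per_class$support[1],
            support_1 = mt$per_class$support[2],
            accuracy = mt$accuracy,
            precision_0 = mt$per_class$precision[1],
            recall_0 = mt$per_class$recall[1], f1_0 = f1s[["0"]],
            precision_1 = mt$per_class$precision[2],
            recall_1 = mt$per_class$recall[2], f1_1 = f1s[["1"]],
            macro_f1 = unname(mt$macro["f1"]),
            weighted_f1 = unname(mt$weighted["f1"]),
            minority_f1 = f1s[[minority_class]], failed = FALSE))
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  })))
}
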