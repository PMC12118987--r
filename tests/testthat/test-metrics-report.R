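test_that("confusion counts every (true, predicted) pair", {
  cm <- confusion(c(0, 0, 1, 1, 1), c(0, 0, 1, 1, 1))
  expect_equal(unname(diag(cm)), c(2, 3))
  expect_equal(summarize_confusion(cm)$accuracy, 1)

  # all-majority predictor on a 29/9 test set: trace 29, one column
  y <- c(rep(0, 29), rep(1, 9))
  cm0 <- confusion(y, rep(0, 38))
  expect_equal(sum(diag(cm0)), 29)
  expect_equal(unname(cm0[, "1"]), c(0, 0))
  expect_equal(unname(cm0[, "0"]), c(29, 9))

  # brute-force recount on random vectors
  set.seed(4)
  for (i in 1:10) {
    yt <- rbinom(25, 1, 0.4); yp <- rbinom(25, 1, 0.6)
    cm <- confusion(yt, yp)
    for (a in 0:1) for (b in 0:1) {
      expect_equal(cm[a + 1, b + 1], sum(yt == a & yp == b))
    }
  }
  expect_error(confusion(0:1, 0), class = "depscreen_config_error")
  expect_error(confusion(c(0, 2), c(0, 1)),
               class = "depscreen_config_error")
})

test_that("f1_from_pr is the harmonic mean with the 0/0 convention", {
  expect_equal(round(f1_from_pr(0.87, 0.93), 2), 0.90)
  expect_equal(round(f1_from_pr(0.40, 0.67), 2), 0.50)
  expect_equal(f1_from_pr(0, 0), 0)
  x <- seq(0, 1, by = 0.1)
  expect_equal(f1_from_pr(x, x), x)
  # bounds: min(p, r) <= F1 <= max(p, r)
  set.seed(2)
  p <- runif(200); r <- runif(200)
  f1 <- f1_from_pr(p, r)
  expect_true(all(f1 >= pmin(p, r) - 1e-12))
  expect_true(all(f1 <= pmax(p, r) + 1e-12))
})

test_that("summarize_confusion reproduces published worked examples", {
  # best random-forest confusion matrix: supports 29/9, recalls 0.93/0.56
  rf <- matrix(c(27, 2, 4, 5), 2, 2, byrow = TRUE)
  m <- summarize_confusion(rf)
  expect_equal(round(m$per_class$precision, 2), c(0.87, 0.71))
  expect_equal(round(m$per_class$recall, 2), c(0.93, 0.56))
  expect_equal(round(m$per_class$f1, 2), c(0.90, 0.63))
  expect_equal(round(m$accuracy, 2), 0.84)
  expect_equal(round(unname(m$macro["f1"]), 2), 0.76)
  expect_equal(round(unname(m$weighted["f1"]), 2), 0.83)

  # best svm confusion matrix
  svm <- matrix(c(20, 9, 3, 6), 2, 2, byrow = TRUE)
  ms <- summarize_confusion(svm)
  expect_equal(round(ms$per_class$f1, 2), c(0.77, 0.50))
  expect_equal(round(ms$accuracy, 2), 0.68)
  expect_equal(round(unname(ms$weighted["f1"]), 2), 0.71)

  # degenerate all-majority predictor
  deg <- matrix(c(29, 0, 9, 0), 2, 2, byrow = TRUE)
  md <- summarize_confusion(deg)
  expect_equal(round(unname(md$macro["f1"]), 2), 0.43)
  expect_equal(round(unname(md$weighted["recall"]), 2), 0.76)
  expect_equal(md$per_class$f1[2], 0)
})

test_that("metric identities hold for random confusion matrices", {
  set.seed(8)
  for (i in 1:50) {
    cm <- matrix(rpois(4, 8), 2, 2)
    if (sum(cm) == 0) next
    m <- summarize_confusion(cm)
    # accuracy = support-weighted mean recall, exactly
    expect_equal(m$accuracy, unname(m$weighted["recall"]))
    # weighted F1 between the class F1s; macro F1 is their midpoint
    expect_gte(unname(m$weighted["f1"]), min(m$per_class$f1) - 1e-12)
    expect_lte(unname(m$weighted["f1"]), max(m$per_class$f1) + 1e-12)
    expect_equal(unname(m$macro["f1"]), mean(m$per_class$f1))
  }
  # single-class test set: weighted metrics equal that class's metrics
  one <- summarize_confusion(matrix(c(7, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(one$weighted["f1"]), one$per_class$f1[1])
  expect_equal(unname(one$weighted["recall"]), one$per_class$recall[1])
})

fake_results <- function(accuracy, minority_f1, n_features = 2,
                         subset = NULL) {
  n <- length(accuracy)
  tibble::tibble(
    family = "svm", params = "{}",
    n_features = rep_len(n_features, n),
    subset = subset %||% paste0("s", seq_len(n)),
    accuracy = accuracy, minority_f1 = minority_f1,
    failed = FALSE)
}

test_that("selection prefers constrained accuracy over raw accuracy", {
  res <- fake_results(accuracy = c(0.76, 0.68),
                      minority_f1 = c(0, 0.50))
  sel <- select_best(res, selection_policy())
  expect_false(sel$constrained_empty)
  expect_equal(sel$winner$accuracy, 0.68)
  expect_equal(sel$winner$minority_f1, 0.50)

  single <- select_best(fake_results(0.7, 0.4))
  expect_equal(single$winner$accuracy, 0.7)

  expect_error(select_best(fake_results(numeric(0), numeric(0))),
               class = "depscreen_config_error")
})

test_that("all-discarded selections flag constrained_empty", {
  res <- fake_results(accuracy = c(0.76, 0.70), minority_f1 = c(0, 0))
  sel <- select_best(res)
  expect_true(sel$constrained_empty)
  expect_null(sel$winner)
  expect_equal(nrow(sel$ranking), 2)
  # argmax mode keeps only best-minority-F1 candidates
  res2 <- fake_results(accuracy = c(0.9, 0.6, 0.7),
                       minority_f1 = c(0.2, 0.5, 0.5))
  sel2 <- select_best(res2, selection_policy(constraint = "argmax"))
  expect_equal(sel2$winner$accuracy, 0.7)
})

test_that("selection equals a brute-force scan under the same total order", {
  set.seed(14)
  n <- 200
  res <- fake_results(
    accuracy = round(runif(n), 2),
    minority_f1 = round(runif(n), 2),
    n_features = sample(2:5, n, replace = TRUE),
    subset = replicate(n, paste(sample(letters, 3), collapse = ",")))
  policy <- selection_policy(min_minority_f1 = 0.3)
  sel <- select_best(res, policy)

  # independent scan: explicit pairwise comparison
  better <- function(i, j) {
    if (res$accuracy[i] != res$accuracy[j])
      return(res$accuracy[i] > res$accuracy[j])
    if (res$minority_f1[i] != res$minority_f1[j])
      return(res$minority_f1[i] > res$minority_f1[j])
    if (res$n_features[i] != res$n_features[j])
      return(res$n_features[i] < res$n_features[j])
    res$subset[i] < res$subset[j]
  }
  eligible <- which(res$minority_f1 > 0.3)
  best <- eligible[1]
  for (i in eligible[-1]) if (better(i, best)) best <- i
  expect_equal(sel$winner$accuracy, res$accuracy[best])
  expect_equal(sel$winner$subset, res$subset[best])
  expect_equal(nrow(sel$ranking), length(eligible))
  # never returns a candidate below the floor when survivors exist
  expect_true(all(sel$ranking$minority_f1 > 0.3))
})

test_that("rendered reports are deterministic and ordered by the policy", {
  res <- fake_results(
    accuracy = c(0.8, 0.9, 0.7, 0.9, 0.6),
    minority_f1 = c(0.5, 0.4, 0.6, 0.7, 0))
  sel <- select_best(res)
  baseline <- list(class_0 = 0.76, class_1 = 0.24)
  d1 <- tempfile(); d2 <- tempfile()
  render_report(res, baseline, sel, d1)
  render_report(res, baseline, sel, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "ranking.csv")),
                   readLines(file.path(d2, "ranking.csv")))
  report <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(length(report$top_candidates), min(5, nrow(sel$ranking)))
  top_acc <- vapply(report$top_candidates, function(x) x$accuracy,
                    numeric(1))
  expect_equal(top_acc, sel$ranking$accuracy[seq_along(top_acc)])

  # empty constrained ranking still renders, with the baseline only
  empty_sel <- select_best(fake_results(0.76, 0))
  d3 <- tempfile()
  render_report(fake_results(0.76, 0), baseline, empty_sel, d3)
  rep3 <- jsonlite::read_json(file.path(d3, "report.json"))
  expect_true(rep3$constrained_empty)
  expect_null(rep3$winner)
  expect_equal(rep3$baseline$class_0, 0.76)
})
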