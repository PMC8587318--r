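test_that("perfect predictions score 1.0 on every metric", {
  blobs <- make_blobs(k = 3, n_per = 15, sep = 40, seed = 41)
  d <- labeled_dataset(blobs$x, paste0("c", blobs$planted))
  m <- train_flat(d, classifier_spec("knn"))
  r <- evaluate(m, d)
  expect_equal(r$accuracy, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)
  expect_true(all(r$per_class_confusion[upper.tri(r$per_class_confusion)] == 0))
  expect_true(all(r$per_class_confusion[lower.tri(r$per_class_confusion)] == 0))
})

test_that("hand-computed two-class counts give the known macro metrics", {
  truth <- factor(rep(c("x", "y"), times = c(10, 10)),
                  levels = c("x", "y"))
  pred <- factor(c(rep("x", 8), rep("y", 2), rep("x", 4), rep("y", 6)),
                 levels = c("x", "y"))
  r <- metrics_from_predictions(truth, pred)
  expect_equal(unclass(r$per_class_confusion),
               matrix(c(8L, 4L, 2L, 6L), 2, 2), ignore_attr = TRUE)
  expect_equal(r$accuracy, 0.70)
  expect_equal(r$precision, (8 / 12 + 6 / 8) / 2)
  expect_equal(r$recall, (8 / 10 + 6 / 10) / 2)
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
})

test_that("label-independent predictions hit chance accuracy on balanced data", {
  set.seed(55)
  L <- paste0("a", 1:6)
  n <- 3000
  truth <- factor(rep(L, each = n / 6), levels = L)
  pred <- factor(sample(L, n, replace = TRUE), levels = L)
  r <- metrics_from_predictions(truth, pred)
  # binomial 4-sigma band around 1/6 at n = 3000
  expect_lt(abs(r$accuracy - 1 / 6), 4 * sqrt((1 / 6) * (5 / 6) / n))
})

test_that("macro F1 is invariant under class relabeling, accuracy under row order", {
  set.seed(66)
  L <- c("p", "q", "r")
  truth <- factor(sample(L, 120, replace = TRUE), levels = L)
  pred <- factor(sample(L, 120, replace = TRUE), levels = L)
  r <- metrics_from_predictions(truth, pred)
  swap <- c(p = "r", q = "q", r = "p")
  r_swapped <- metrics_from_predictions(
    factor(swap[as.character(truth)], levels = L),
    factor(swap[as.character(pred)], levels = L))
  expect_equal(r_swapped$f1, r$f1)
  expect_equal(r_swapped$accuracy, r$accuracy)
  perm <- sample(120)
  r_perm <- metrics_from_predictions(truth[perm], pred[perm])
  expect_equal(r_perm$accuracy, r$accuracy)
})

test_that("classes never predicted trigger the zero-division guard", {
  truth <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "c"))
  pred <- factor(c("a", "a", "a", "b"), levels = c("a", "b", "c"))
  expect_warning(r <- metrics_from_predictions(truth, pred), "macro")
  expect_equal(r$accuracy, 0.75)
  # class c contributes 0 to both macro averages
  expect_equal(r$precision, (2 / 3 + 1 + 0) / 3)
})

test_that("empty or inconsistent test sets are rejected", {
  d <- make_overlap_dataset(seed = 1)
  m <- train_flat(d, classifier_spec("knn"))
  other <- labeled_dataset(matrix(rnorm(8), 4, 2),
                           c("a", "b", "zz", "zz"))
  expect_error(evaluate(m, other), "zz")
})

test_that("a singleton sweep equals the direct fit-and-evaluate", {
  draw <- generate(synthetic_spec(seed = 43, n_per_class = 40,
                                  n_test_per_class = 25))
  base <- list(part_spec = partition_spec(seed = 3), theta = 0.01,
               top_spec = classifier_spec("naive_bayes", seed = 1))
  sw <- run_sweep(draw$train, draw$test, base, "threshold", 0.02)
  direct <- evaluate(
    fit_pipeline(draw$train, part_spec = base$part_spec, theta = 0.02,
                 top_spec = base$top_spec, second_spec = base$top_spec),
    draw$test)
  expect_equal(nrow(sw$metrics), 1)
  expect_equal(sw$metrics$accuracy, direct$accuracy)
  expect_equal(sw$metrics$f1, direct$f1)
})

test_that("the threshold sweep keeps the set-inclusion chain across rows", {
  draw <- generate(synthetic_spec(seed = 47, n_per_class = 60,
                                  n_test_per_class = 30))
  grid <- c(0.005, 0.01, 0.02, 0.03, 0.05, 0.1, 0.5)
  sw <- run_sweep(draw$train, draw$test,
                  list(part_spec = partition_spec(seed = 2)),
                  "threshold", grid)
  expect_equal(nrow(sw$metrics), 7)
  expect_equal(sw$metrics$axis_value, as.character(grid))
  for (i in seq_len(length(grid) - 1)) {
    s_lo <- sw$provenance[[i]]$sets
    s_hi <- sw$provenance[[i + 1]]$sets
    for (a in names(s_lo)) {
      expect_true(all(s_hi[[a]] %in% s_lo[[a]]),
                  info = sprintf("row %d -> %d, %s", i, i + 1, a))
    }
  }
})

test_that("a sweep row whose sets are empty matches the flat model exactly", {
  # widely separated classes -> pure clusters -> all ratios on the diagonal
  blobs <- make_blobs(k = 3, n_per = 30, sep = 60, seed = 53)
  train <- labeled_dataset(blobs$x, paste0("c", blobs$planted))
  test_blobs <- make_blobs(k = 3, n_per = 10, sep = 60, seed = 54)
  test <- labeled_dataset(test_blobs$x, paste0("c", test_blobs$planted))
  sw <- run_sweep(train, test,
                  list(part_spec = partition_spec(seed = 1),
                       top_spec = classifier_spec("naive_bayes", seed = 1)),
                  "threshold", 0.5)
  off <- sw$provenance[[1]]$ratios; diag(off) <- 0
  expect_lt(max(off), 0.5)
  flat <- evaluate(train_flat(train,
                              classifier_spec("naive_bayes", seed = 1)),
                   test)
  expect_equal(sw$reports[[1]]$accuracy, flat$accuracy)
  expect_equal(sw$reports[[1]]$per_class_confusion,
               flat$per_class_confusion)
})

test_that("sweep axes validate values before any fitting", {
  draw <- generate(synthetic_spec(seed = 3, n_per_class = 20,
                                  n_test_per_class = 10))
  expect_error(run_sweep(draw$train, draw$test, list(), "threshold",
                         c(0.01, 7)), "illegal value")
  expect_error(run_sweep(draw$train, draw$test, list(), "distance_metric",
                         "manhattan"), "illegal value")
  expect_error(run_sweep(draw$train, draw$test, list(), "threshold",
                         numeric(0)), "non-empty")
  expect_error(run_sweep(draw$train, draw$test, list(), "classifier_pair",
                         list(c("naive_bayes", "cnn"))), "illegal value")
})

test_that("classifier-pair sweep trains the requested heterogeneous pairs", {
  draw <- generate(synthetic_spec(seed = 59, n_per_class = 40,
                                  n_test_per_class = 20))
  pairs <- list(c("naive_bayes", "naive_bayes"),
                c("naive_bayes", "svm_linear"))
  sw <- run_sweep(draw$train, draw$test,
                  list(part_spec = partition_spec(seed = 2), theta = 0.02),
                  "classifier_pair", pairs)
  expect_equal(sw$metrics$axis_value,
               c("naive_bayes-naive_bayes", "naive_bayes-svm_linear"))
  expect_equal(nrow(sw$metrics), 2)
})

test_that("metrics TSV uses percentage rows with two decimals", {
  r <- metrics_from_predictions(
    factor(c("a", "a", "b", "b")), factor(c("a", "b", "b", "b")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_tsv(list(`NB-SVM` = r), f)
  got <- read.delim(f, check.names = FALSE)
  expect_equal(got$Metric, c("Accuracy", "Precision", "Recall", "F1"))
  expect_equal(got[["NB-SVM"]][1], 75.00)
})
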