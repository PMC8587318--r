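empty_sets <- function(L) {
  structure(stats::setNames(lapply(L, function(a) character(0)), L),
            theta = 0.5, class = "confusing_set_map")
}

make_sets <- function(L, pairs, theta = 0.02) {
  s <- stats::setNames(lapply(L, function(a) character(0)), L)
  for (a in names(pairs)) s[[a]] <- pairs[[a]]
  structure(s, theta = theta, class = "confusing_set_map")
}

test_that("empty confusing sets yield a recognizer with no second level", {
  d <- make_overlap_dataset(seed = 2)
  m <- train_hierarchical(d, empty_sets(d$label_set))
  expect_length(m$second_models, 0)
  pred <- predict(m, d$features)
  expect_false(any(pred$routed))
  flat <- train_flat(d, m$top_spec)
  expect_identical(as.character(pred$final_label),
                   as.character(predict(flat, d$features)))
  expect_identical(pred$final_label, pred$top_level_label)
})

test_that("second-level inventory and training subsets follow the sets", {
  d <- make_overlap_dataset(seed = 3, n_per = 25)
  sets <- make_sets(d$label_set, list(a = "b", b = "a"))
  m <- train_hierarchical(d, sets, classifier_spec("naive_bayes"),
                          classifier_spec("knn"))
  expect_setequal(names(m$second_models), c("a", "b"))
  for (a in c("a", "b")) {
    expect_setequal(m$second_models[[a]]$classes, c("a", "b"))
    # the lazy k-NN back end stores its training subset: exactly n_a + n_b
    expect_equal(nrow(m$second_models[[a]]$fit$x), 50)
  }
  expect_equal(m$second_spec$family, "knn")
  expect_equal(m$top_spec$family, "naive_bayes")
})

test_that("packaged-matrix sets at theta 0.01 give the expected inventory", {
  cm <- ucihar_confusion_fixture()
  sets <- confusing_sets(cm, 0.01)
  draw <- generate(synthetic_spec(seed = 5, n_per_class = 30,
                                  n_test_per_class = 10))
  m <- train_hierarchical(draw$train, sets)
  expect_setequal(names(m$second_models),
                  c("go-upstairs", "go-downstairs", "standing", "lying"))
  expect_setequal(m$second_models[["standing"]]$classes,
                  c("standing", "sitting", "lying"))
})

test_that("routed labels stay inside the top label's refinement set", {
  draw <- generate(synthetic_spec(seed = 9, n_per_class = 60,
                                  n_test_per_class = 40))
  m <- fit_pipeline(draw$train, part_spec = partition_spec(seed = 9),
                    theta = 0.02)
  pred <- predict(m, draw$test$features)
  sets <- m$confusing_sets
  for (i in seq_len(nrow(pred))) {
    top <- as.character(pred$top_level_label[i])
    fin <- as.character(pred$final_label[i])
    if (pred$routed[i]) {
      expect_true(fin %in% c(top, sets[[top]]))
    } else {
      expect_identical(fin, top)
    }
  }
  expect_equal(pred$routed,
               as.character(pred$top_level_label) %in%
                 names(m$second_models))
})

test_that("predict equals manual two-step routing on random rows", {
  draw <- generate(synthetic_spec(seed = 13, n_per_class = 50,
                                  n_test_per_class = 20))
  m <- fit_pipeline(draw$train, part_spec = partition_spec(seed = 13),
                    theta = 0.02,
                    top_spec = classifier_spec("decision_tree"),
                    second_spec = classifier_spec("svm_linear"))
  set.seed(77)
  rows <- draw$test$features[sample(n_samples(draw$test), 100), ]
  pred <- predict(m, rows)
  expect_equal(as.character(pred$final_label), manual_route(m, rows))
})

test_that("fit_pipeline equals the manually chained components", {
  draw <- generate(synthetic_spec(seed = 17, n_per_class = 40,
                                  n_test_per_class = 20))
  ps <- partition_spec(seed = 4)
  ts <- classifier_spec("naive_bayes", seed = 2)
  ss <- classifier_spec("knn", seed = 3)
  auto <- fit_pipeline(draw$train, part_spec = ps, theta = 0.02,
                       top_spec = ts, second_spec = ss)
  part <- partition_dataset(draw$train, ps)
  cm <- activity_confusion_matrix(draw$train, part)
  manual <- train_hierarchical(draw$train, confusing_sets(cm, 0.02), ts, ss)
  pa <- predict(auto, draw$test$features)
  pm <- predict(manual, draw$test$features)
  expect_identical(pa$final_label, pm$final_label)
  expect_equal(auto$provenance$cm, cm)
  expect_identical(lapply(auto$confusing_sets, identity),
                   lapply(manual$confusing_sets, identity))
})

test_that("theta above the maximum off-diagonal ratio reduces to the flat model", {
  draw <- generate(synthetic_spec(seed = 23, n_per_class = 40,
                                  n_test_per_class = 30))
  m <- fit_pipeline(draw$train, part_spec = partition_spec(seed = 23),
                    theta = 1.0)
  eta <- m$provenance$ratios
  off <- eta; diag(off) <- 0
  expect_lt(max(off), 1)
  expect_length(m$second_models, 0)
  flat <- train_flat(draw$train, m$top_spec)
  expect_identical(as.character(predict(m, draw$test$features)$final_label),
                   as.character(predict(flat, draw$test$features)))
})

test_that("the same seed and config reproduce inventory and predictions", {
  draw <- generate(synthetic_spec(seed = 29, n_per_class = 40,
                                  n_test_per_class = 20))
  fit2 <- function() fit_pipeline(
    draw$train, part_spec = partition_spec(seed = 6), theta = 0.02,
    top_spec = classifier_spec("naive_bayes", seed = 1),
    second_spec = classifier_spec("svm_linear", seed = 1))
  m1 <- fit2(); m2 <- fit2()
  expect_identical(names(m1$second_models), names(m2$second_models))
  expect_identical(predict(m1, draw$test$features),
                   predict(m2, draw$test$features))
})

test_that("homogeneous NB pairing differs from flat NB only on routed rows", {
  draw <- generate(synthetic_spec(seed = 31))
  m <- fit_pipeline(draw$train, part_spec = partition_spec(seed = 31),
                    theta = 0.02,
                    top_spec = classifier_spec("naive_bayes"))
  flat <- train_flat(draw$train, m$top_spec)
  pred <- predict(m, draw$test$features)
  pf <- predict(flat, draw$test$features)
  changed <- as.character(pred$final_label) != as.character(pf)
  expect_true(all(pred$routed[changed]))
})

test_that("confusing-set members missing from the data are a consistency error", {
  d <- make_overlap_dataset(seed = 5)
  sets <- make_sets(c(d$label_set, "jogging"),
                    list(a = "jogging"))
  expect_error(train_hierarchical(d, sets), "jogging")
})

test_that("model bundles round-trip through disk", {
  draw <- generate(synthetic_spec(seed = 37, n_per_class = 30,
                                  n_test_per_class = 10))
  m <- fit_pipeline(draw$train, part_spec = partition_spec(seed = 37),
                    theta = 0.02)
  dir <- withr::local_tempdir()
  write_model_bundle(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "confusion_matrix.tsv")))
  m2 <- read_model_bundle(dir)
  expect_identical(predict(m2, draw$test$features),
                   predict(m, draw$test$features))
})
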