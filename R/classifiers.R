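#' Classifier specification
#'
#' Names a base-learner family and its hyperparameters. Defaults follow
#' the framework's standard instantiation: 1-nearest-neighbor with
#' Euclidean distance, linear-kernel SVM with cost 1, Gaussian naive
#' Bayes, and an unpruned decision tree (Gini impurity, unlimited depth).
#'
#' @param family One of `"naive_bayes"`, `"knn"`, `"svm_linear"`,
#'   `"decision_tree"`.
#' @param neighbors k for the k-nearest-neighbor family (default 1).
#' @param cost Regularization constant for the linear SVM (default 1).
#' @param min_split,complexity Decision-tree controls passed to the rpart
#'   back end; the defaults (2, 0) grow a fully developed tree.
#' @param seed Integer seed pinning any stochastic step in training or
#'   distance tie-breaking.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("naive_bayes", "knn", "svm_linear",
                                       "decision_tree"),
                            neighbors = 1L, cost = 1,
                            min_split = 2L, complexity = 0,
                            seed = 1L) {
  family <- match.arg(family)
  stopifnot(neighbors >= 1, cost > 0, min_split >= 1)
  structure(
    list(family = family, neighbors = as.integer(neighbors), cost = cost,
         min_split = as.integer(min_split), complexity = complexity,
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

# canonical column names used for the formula-based back ends so that
# arbitrary (possibly non-syntactic) user feature names never reach rpart
# or naiveBayes
canonical_frame <- function(x) {
  df <- as.data.frame(x)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  df
}

#' Train a flat (single-step) activity recognizer
#'
#' Fits one classifier over the full label set — the conventional one-step
#' model the hierarchical recognizer is compared against, and the building
#' block used at both levels of the hierarchy.
#'
#' @param dataset A [labeled_dataset()] with at least two classes present.
#' @param spec A [classifier_spec()].
#' @return An object of class `flat_recognizer` with a [predict()] method
#'   returning a factor over the training label set.
#' @export
train_flat <- function(dataset, spec = classifier_spec()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(spec, "classifier_spec"))
  y <- droplevels(dataset$labels)
  if (nlevels(y) < 2) {
    stop("training data contains a single class; nothing to discriminate",
         call. = FALSE)
  }
  x <- dataset$features
  if (spec$family == "knn" && min(table(y)) < spec$neighbors) {
    stop(sprintf("every class needs >= %d samples for %d-nearest-neighbor",
                 spec$neighbors, spec$neighbors), call. = FALSE)
  }
  fit <- with_seed(spec$seed, switch(spec$family,
    naive_bayes = e1071::naiveBayes(canonical_frame(x), y),
    # k-NN is lazy: store the training set
    knn = list(x = x, y = y),
    svm_linear = e1071::svm(x, y, kernel = "linear", cost = spec$cost,
                            scale = FALSE),
    decision_tree = {
      df <- canonical_frame(x)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     minsplit = spec$min_split, cp = spec$complexity,
                     xval = 0))
    }
  ))
  structure(
    list(fit = fit, spec = spec, classes = levels(y),
         label_set = dataset$label_set, n_features = ncol(x)),
    class = "flat_recognizer"
  )
}

#' @export
print.flat_recognizer <- function(x, ...) {
  cat(sprintf("flat_recognizer: %s over {%s}\n", x$spec$family,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict activities with a flat recognizer
#'
#' @param object A `flat_recognizer`.
#' @param newdata Numeric matrix whose column count matches the training
#'   feature width.
#' @param ... Unused.
#' @return Factor of predicted activities with levels equal to the full
#'   training label set.
#' @export
predict.flat_recognizer <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(newdata), object$n_features), call. = FALSE)
  }
  spec <- object$spec
  pred <- with_seed(spec$seed + 1L, switch(spec$family,
    naive_bayes = as.character(
      predict(object$fit, canonical_frame(newdata), type = "class")),
    knn = as.character(
      class::knn(object$fit$x, newdata, object$fit$y, k = spec$neighbors)),
    svm_linear = as.character(predict(object$fit, newdata)),
    decision_tree = as.character(
      predict(object$fit, canonical_frame(newdata), type = "class"))
  ))
  bad <- setdiff(unique(pred), object$label_set)
  if (length(bad) > 0) {
    stop(sprintf("classifier emitted unknown label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  factor(pred, levels = object$label_set)
}
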