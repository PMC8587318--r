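#' Recognition metrics on a test set
#'
#' Computes the per-class prediction confusion matrix (true activity in
#' rows, predicted in columns) and accuracy, macro-averaged precision and
#' recall, and F1. Macro averaging weights every class of the training
#' label set equally; F1 is the harmonic mean of macro precision and
#' macro recall (not the mean of per-class F1 scores — the two differ).
#' Classes with no predicted (or no true) samples contribute a guarded
#' precision (recall) of 0, with a warning.
#'
#' @param model A `flat_recognizer` or `hierarchical_recognizer`.
#' @param test A [labeled_dataset()] whose labels are a subset of the
#'   model's label set.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (fractions in \[0, 1\]) and
#'   `per_class_confusion`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(test, "labeled_dataset"))
  if (n_samples(test) == 0) stop("empty test set", call. = FALSE)
  L <- if (inherits(model, "hierarchical_recognizer")) model$label_set
       else model$label_set
  extra <- setdiff(unique(as.character(test$labels)), L)
  if (length(extra) > 0) {
    stop(sprintf("test labels absent from the training label set: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  pred <- if (inherits(model, "hierarchical_recognizer")) {
    predict(model, test$features)$final_label
  } else {
    predict(model, test$features)
  }
  metrics_from_predictions(factor(as.character(test$labels), levels = L),
                           factor(as.character(pred), levels = L))
}

#' Metrics from a pair of label vectors
#'
#' @param truth,pred Factors over the same level set.
#' @return A `metrics_report`.
#' @export
metrics_from_predictions <- function(truth, pred) {
  stopifnot(identical(levels(truth), levels(pred)))
  conf <- table(true = truth, predicted = pred)
  conf <- matrix(as.integer(conf), nrow(conf), ncol(conf),
                 dimnames = dimnames(conf))
  total <- sum(conf)
  tp <- diag(conf)
  col_tot <- colSums(conf)
  row_tot <- rowSums(conf)
  if (any(col_tot == 0) || any(row_tot == 0)) {
    warning("some classes have no predicted or no true samples; ",
            "their precision/recall contribute 0 to the macro average",
            call. = FALSE)
  }
  prec_c <- ifelse(col_tot == 0, 0, tp / col_tot)
  rec_c <- ifelse(row_tot == 0, 0, tp / row_tot)
  precision <- mean(prec_c)
  recall <- mean(rec_c)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(accuracy = sum(tp) / total, precision = precision,
         recall = recall, f1 = f1, per_class_confusion = conf),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report: accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

sweep_axes <- c("threshold", "cluster_count_offset", "distance_metric",
                "clustering_algorithm", "classifier_pair")

#' Sensitivity sweep over one pipeline parameter
#'
#' Rebuilds and evaluates the full pipeline once per candidate value,
#' changing only the swept field of the base configuration (all seeds
#' fixed), and tabulates the metrics. Per-row provenance (confusion
#' matrix, ratios, confusing sets) is retained so properties like
#' threshold monotonicity are mechanically checkable.
#'
#' @param train,test [labeled_dataset()]s.
#' @param base_config List with elements `part_spec` ([partition_spec()]),
#'   `theta`, `top_spec` and `second_spec` ([classifier_spec()]s); missing
#'   elements take the package defaults.
#' @param axis One of `"threshold"`, `"cluster_count_offset"`,
#'   `"distance_metric"`, `"clustering_algorithm"`, `"classifier_pair"`.
#' @param values Non-empty vector (list for `classifier_pair`, whose
#'   elements are `c(top_family, second_family)` pairs).
#' @return An object of class `sweep_result`: list with `axis`, `values`,
#'   `metrics` (data frame, one row per value in request order), `reports`
#'   and `provenance` (lists parallel to `values`).
#' @export
run_sweep <- function(train, test, base_config = list(), axis, values) {
  axis <- match.arg(axis, sweep_axes)
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  cfg <- list(
    part_spec = base_config$part_spec %||% partition_spec(),
    theta = base_config$theta %||% 0.01,
    top_spec = base_config$top_spec %||% classifier_spec(),
    second_spec = base_config$second_spec %||% base_config$top_spec %||%
      classifier_spec()
  )
  # validate every value before any fitting
  for (v in values) validate_axis_value(axis, v)

  reports <- vector("list", length(values))
  prov <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- if (is.list(values)) values[[i]] else values[i]
    cfg_i <- apply_axis_value(cfg, axis, v)
    model <- fit_pipeline(train, part_spec = cfg_i$part_spec,
                          theta = cfg_i$theta, top_spec = cfg_i$top_spec,
                          second_spec = cfg_i$second_spec)
    reports[[i]] <- evaluate(model, test)
    prov[[i]] <- model$provenance
  }
  metrics <- data.frame(
    axis_value = vapply(seq_along(values), function(i) {
      v <- if (is.list(values)) values[[i]] else values[i]
      paste(v, collapse = "-")
    }, character(1)),
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    precision = vapply(reports, `[[`, numeric(1), "precision"),
    recall = vapply(reports, `[[`, numeric(1), "recall"),
    f1 = vapply(reports, `[[`, numeric(1), "f1")
  )
  structure(list(axis = axis, values = values, metrics = metrics,
                 reports = reports, provenance = prov),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result over %s (%d settings):\n", x$axis,
              nrow(x$metrics)))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

classifier_families <- c("naive_bayes", "knn", "svm_linear", "decision_tree")

validate_axis_value <- function(axis, v) {
  ok <- switch(axis,
    threshold = is.numeric(v) && length(v) == 1 && v > 0 && v <= 1,
    cluster_count_offset = is.numeric(v) && length(v) == 1 &&
      v == as.integer(v),
    distance_metric = is.character(v) && length(v) == 1 &&
      v %in% c("euclidean", "cosine", "correlation"),
    clustering_algorithm = is.character(v) && length(v) == 1 &&
      v %in% c("kmeans", "kmedoids", "agglomerative"),
    classifier_pair = is.character(v) && length(v) == 2 &&
      all(v %in% classifier_families)
  )
  if (!ok) {
    stop(sprintf("illegal value for sweep axis '%s': %s", axis,
                 paste(v, collapse = "-")), call. = FALSE)
  }
  invisible(TRUE)
}

apply_axis_value <- function(cfg, axis, v) {
  ps <- cfg$part_spec
  switch(axis,
    threshold = cfg$theta <- v,
    cluster_count_offset = cfg$part_spec <- partition_spec(
      ps$algorithm, ps$metric, cluster_count_offset = as.integer(v),
      seed = ps$seed, max_iterations = ps$max_iterations,
      n_restarts = ps$n_restarts, scale = ps$scale),
    distance_metric = cfg$part_spec <- partition_spec(
      ps$algorithm, metric = v,
      cluster_count_offset = ps$cluster_count_offset, seed = ps$seed,
      max_iterations = ps$max_iterations, n_restarts = ps$n_restarts,
      scale = ps$scale),
    clustering_algorithm = cfg$part_spec <- partition_spec(
      algorithm = v, metric = ps$metric,
      cluster_count_offset = ps$cluster_count_offset, seed = ps$seed,
      max_iterations = ps$max_iterations, n_restarts = ps$n_restarts,
      scale = ps$scale),
    classifier_pair = {
      cfg$top_spec <- classifier_spec(v[1], seed = cfg$top_spec$seed)
      cfg$second_spec <- classifier_spec(v[2], seed = cfg$second_spec$seed)
    }
  )
  cfg
}

#' Write a metrics table as TSV
#'
#' One column per model/setting, metric rows (Accuracy, Precision, Recall,
#' F1) as percentages with two decimals — the conventional report layout
#' for recognizer comparisons.
#'
#' @param reports Named list of `metrics_report`s; names become columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(reports, path) {
  stopifnot(length(reports) > 0, !is.null(names(reports)))
  m <- vapply(reports, function(r)
    c(Accuracy = r$accuracy, Precision = r$precision,
      Recall = r$recall, F1 = r$f1) * 100, numeric(4))
  df <- data.frame(Metric = rownames(m),
                   format(round(m, 2), nsmall = 2),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
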