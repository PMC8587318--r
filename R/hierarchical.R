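#' Train a clustering-guided two-level activity recognizer
#'
#' The top-level classifier discriminates all activities (identical in
#' construction to the flat model). For every activity `L_A` whose
#' confusing set `S(L_A)` is non-empty, a second-level classifier is
#' trained on exactly the training samples whose true label lies in
#' `{L_A} U S(L_A)`, with the full original feature vector and no
#' reweighting. The top and second levels may use different classifier
#' families (heterogeneous pairing, e.g. naive Bayes on top, SVM below).
#'
#' @param dataset A [labeled_dataset()].
#' @param sets A [confusing_sets()] map; every activity it mentions must
#'   belong to the dataset's label set.
#' @param top_spec [classifier_spec()] for the top-level model.
#' @param second_spec [classifier_spec()] for the second-level models;
#'   defaults to `top_spec` (homogeneous pairing).
#' @return An object of class `hierarchical_recognizer` holding the top
#'   model, the per-activity second-level models (keyed by activities with
#'   non-empty confusing sets only), the confusing-set map and the label
#'   set.
#' @export
train_hierarchical <- function(dataset, sets,
                               top_spec = classifier_spec(),
                               second_spec = top_spec) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(sets, "confusing_set_map"),
            inherits(top_spec, "classifier_spec"),
            inherits(second_spec, "classifier_spec"))
  L <- dataset$label_set
  mentioned <- union(names(sets), unlist(sets, use.names = FALSE))
  missing_acts <- setdiff(mentioned, L)
  if (length(missing_acts) > 0) {
    stop(sprintf("confusing-set activities absent from the dataset: %s",
                 paste(missing_acts, collapse = ", ")), call. = FALSE)
  }
  top_model <- train_flat(dataset, top_spec)
  second <- list()
  for (a in names(sets)) {
    s_a <- sets[[a]]
    if (length(s_a) == 0) next
    members <- c(a, s_a)
    idx <- which(as.character(dataset$labels) %in% members)
    sub <- subset_samples(dataset, idx)
    second[[a]] <- train_flat(sub, second_spec)
  }
  structure(
    list(top_model = top_model, second_models = second,
         confusing_sets = sets, label_set = L,
         top_spec = top_spec, second_spec = second_spec,
         provenance = NULL),
    class = "hierarchical_recognizer"
  )
}

#' @export
print.hierarchical_recognizer <- function(x, ...) {
  cat(sprintf(
    "hierarchical_recognizer: %s top level over %d activities, %s second level\n",
    x$top_spec$family, length(x$label_set), x$second_spec$family))
  if (length(x$second_models) == 0) {
    cat("  no second-level models (all confusing sets empty)\n")
  } else {
    for (a in names(x$second_models)) {
      cat(sprintf("  %s -> refines {%s}\n", a,
                  paste(c(a, x$confusing_sets[[a]]), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Route predictions through the two-level recognizer
#'
#' Each sample is first labeled by the top-level classifier. When the
#' top-level label has a non-empty confusing set, the matching
#' second-level classifier re-decides among that label and its confusers
#' and its output is final; otherwise the top-level label is final.
#'
#' @param object A `hierarchical_recognizer`.
#' @param newdata Numeric matrix (or single feature vector) whose width
#'   matches the training width.
#' @param ... Unused.
#' @return A data frame with one row per sample: `final_label`,
#'   `top_level_label` (both factors over the label set) and `routed`
#'   (logical, `TRUE` when a second-level model decided).
#' @export
predict.hierarchical_recognizer <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  top <- predict(object$top_model, newdata)
  final <- as.character(top)
  routed <- rep(FALSE, length(final))
  for (a in names(object$second_models)) {
    hit <- which(final == a)
    if (length(hit) == 0) next
    refined <- predict(object$second_models[[a]],
                       newdata[hit, , drop = FALSE])
    final[hit] <- as.character(refined)
    routed[hit] <- TRUE
  }
  data.frame(final_label = factor(final, levels = object$label_set),
             top_level_label = top,
             routed = routed)
}

#' Fit the full clustering-guided pipeline
#'
#' Composes the framework end to end: partition the training data,
#' accumulate the activity confusion matrix, derive confusing sets at the
#' threshold, and train the two-level recognizer. The intermediate
#' confusion matrix, ratio matrix, confusing sets and partition are kept
#' in the returned object's `provenance` for inspection.
#'
#' @param dataset Training [labeled_dataset()].
#' @param part_spec A [partition_spec()].
#' @param theta Confusion threshold in (0, 1].
#' @param top_spec,second_spec [classifier_spec()]s for the two levels.
#' @return A `hierarchical_recognizer` with populated `provenance`
#'   (elements `cm`, `ratios`, `sets`, `partition`, `theta`).
#' @export
fit_pipeline <- function(dataset, part_spec = partition_spec(),
                         theta = 0.01,
                         top_spec = classifier_spec(),
                         second_spec = top_spec) {
  part <- partition_dataset(dataset, part_spec)
  cm <- activity_confusion_matrix(dataset, part)
  sets <- confusing_sets(cm, theta)
  model <- train_hierarchical(dataset, sets, top_spec, second_spec)
  model$provenance <- list(cm = cm, ratios = confusion_ratios(cm),
                           sets = sets, partition = part, theta = theta,
                           partition_spec = part_spec)
  model
}

#' Serialize a trained recognizer to a bundle directory
#'
#' Writes a manifest (YAML), the label set, the confusion matrix, ratio
#' matrix and confusing sets as labeled TSV, and the model payloads as RDS
#' files. [read_model_bundle()] restores the recognizer.
#'
#' @param model A `hierarchical_recognizer`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "hierarchical_recognizer"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- model$confusing_sets
  manifest <- list(
    label_set = model$label_set,
    theta = attr(sets, "theta"),
    top_family = model$top_spec$family,
    second_family = model$second_spec$family,
    top_seed = model$top_spec$seed,
    second_seed = model$second_spec$seed,
    second_level_activities = names(model$second_models),
    components = c("manifest.yaml", "confusing_sets.yaml", "model.rds",
                   if (!is.null(model$provenance))
                     c("confusion_matrix.tsv", "confusion_ratios.tsv"))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  yaml::write_yaml(lapply(sets, as.list),
                   file.path(dir, "confusing_sets.yaml"))
  if (!is.null(model$provenance)) {
    write_confusion_tsv(model$provenance$cm,
                        file.path(dir, "confusion_matrix.tsv"))
    write_confusion_tsv(model$provenance$ratios,
                        file.path(dir, "confusion_ratios.tsv"))
  }
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(dir) {
  model <- readRDS(file.path(dir, "model.rds"))
  stopifnot(inherits(model, "hierarchical_recognizer"))
  model
}
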