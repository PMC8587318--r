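#' Labeled activity dataset
#'
#' Bundles a numeric sample-by-feature matrix with one activity label per
#' row and an ordered label set. The ordered label set fixes row/column
#' order in every confusion matrix derived from the data and supplies the
#' deterministic tie-break used when naming a cluster by its majority
#' activity.
#'
#' @param features Numeric matrix (or coercible data frame), one row per
#'   windowed sensor sample, one column per feature. All values must be
#'   finite.
#' @param labels Character or factor vector of activity labels, one per row
#'   of `features`.
#' @param label_set Optional character vector giving the ordered set of
#'   distinct activities. Defaults to the sorted distinct labels. Every
#'   label must be a member.
#' @return An object of class `labeled_dataset` with elements `features`
#'   (numeric matrix), `labels` (factor with levels = `label_set`) and
#'   `label_set`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(12), 6, 2),
#'                      c("walk", "walk", "sit", "sit", "walk", "sit"))
#' d$label_set
#' @export
labeled_dataset <- function(features, labels, label_set = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(features) || any(!is.finite(features))) {
    stop("`features` contains missing or non-finite values", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    stop(sprintf("row count (%d) does not match label count (%d)",
                 nrow(features), length(labels)), call. = FALSE)
  }
  if (is.null(label_set)) label_set <- sort(unique(labels))
  label_set <- as.character(label_set)
  if (anyDuplicated(label_set)) {
    stop("`label_set` contains duplicate activities", call. = FALSE)
  }
  unknown <- setdiff(unique(labels), label_set)
  if (length(unknown) > 0) {
    stop(sprintf("labels not in label_set: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(label_set) < 2) {
    stop("label_set must contain at least two activities", call. = FALSE)
  }
  structure(
    list(features = features,
         labels = factor(labels, levels = label_set),
         label_set = label_set),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features, %d activities\n",
              nrow(x$features), ncol(x$features), length(x$label_set)))
  tab <- table(x$labels)
  cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of samples in a labeled dataset
#' @param d A `labeled_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(d) {
  stopifnot(inherits(d, "labeled_dataset"))
  nrow(d$features)
}

#' Subset a labeled dataset by row
#'
#' @param d A `labeled_dataset`.
#' @param idx Integer or logical row index.
#' @return A `labeled_dataset` restricted to the selected samples; the
#'   ordered label set is preserved even when some activities drop out of
#'   the subset.
#' @export
subset_samples <- function(d, idx) {
  stopifnot(inherits(d, "labeled_dataset"))
  labeled_dataset(d$features[idx, , drop = FALSE],
                  as.character(d$labels[idx]),
                  label_set = d$label_set)
}
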