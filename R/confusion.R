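#' Majority activity of a cluster
#'
#' The activity contributing the most members names the cluster for
#' confusion accounting. Ties are broken deterministically by the earliest
#' position in the ordered label set.
#'
#' @param member_labels Character or factor vector of the cluster members'
#'   true activity labels (non-empty).
#' @param label_set Ordered character vector of all activities; every
#'   member label must belong to it.
#' @return The majority activity, as a character scalar.
#' @examples
#' majority_label(c("sitting", "sitting", "lying"),
#'                c("sitting", "standing", "lying"))
#' @export
majority_label <- function(member_labels, label_set) {
  member_labels <- as.character(member_labels)
  if (length(member_labels) == 0) {
    stop("empty cluster: majority label undefined", call. = FALSE)
  }
  unknown <- setdiff(unique(member_labels), label_set)
  if (length(unknown) > 0) {
    stop(sprintf("labels not in label_set: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  counts <- table(factor(member_labels, levels = label_set))
  # which.max returns the first maximum => earliest label wins ties
  label_set[which.max(counts)]
}

#' Activity confusion matrix from a cluster partition
#'
#' For each cluster, the majority activity names the cluster; every member
#' with true label `L_j` sitting in a cluster named `L_i` contributes one
#' count to entry (row `L_j`, column `L_i`). Summing over all k clusters
#' gives the activity confusion index matrix CM: rows are source (true)
#' activities, columns are target (cluster-majority) activities. Diagonal
#' entries (members whose label is the cluster majority) are kept.
#'
#' @param dataset A [labeled_dataset()].
#' @param part A `cluster_partition` covering exactly the dataset's samples.
#' @return An object of class `activity_confusion`: an integer |L| x |L|
#'   matrix with the ordered label set as dimnames, total entry sum equal
#'   to the number of samples, and row sums equal to per-activity sample
#'   counts.
#' @export
activity_confusion_matrix <- function(dataset, part) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(part, "cluster_partition"))
  n <- n_samples(dataset)
  if (length(part$assignment) != n) {
    stop(sprintf("partition covers %d samples but dataset has %d",
                 length(part$assignment), n), call. = FALSE)
  }
  L <- dataset$label_set
  # per-cluster composition: clusters x activities count table
  comp <- table(cluster = part$assignment, activity = dataset$labels)
  # majority column per cluster; max.col(ties.method = "first") = earliest
  # label in the ordered set, matching majority_label()
  maj <- max.col(comp, ties.method = "first")
  cm <- matrix(0L, length(L), length(L), dimnames = list(L, L))
  for (c_i in seq_len(nrow(comp))) {
    cm[, maj[c_i]] <- cm[, maj[c_i]] + as.integer(comp[c_i, ])
  }
  new_activity_confusion(cm)
}

new_activity_confusion <- function(cm) {
  storage.mode(cm) <- "integer"
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0L),
            !is.null(rownames(cm)), identical(rownames(cm), colnames(cm)))
  structure(cm, class = c("activity_confusion", "matrix", "array"))
}

#' @export
print.activity_confusion <- function(x, ...) {
  cat(sprintf("activity_confusion: %d activities, %d samples\n",
              nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Column-normalized confusion ratios
#'
#' Each confusion-matrix column is divided by its own sum: the entry
#' eta(L_j, L_i) is the share of the samples drawn into clusters named
#' `L_i` that truly belong to `L_j`. Columns that are all zero in CM (an
#' activity that is never a cluster majority) stay all zero by convention,
#' so that activity simply acquires no confusers.
#'
#' @param cm An `activity_confusion` matrix.
#' @return A numeric matrix of the same shape and dimnames, class
#'   `confusion_ratios`; every column either sums to 1 or is all zero.
#' @export
confusion_ratios <- function(cm) {
  stopifnot(inherits(cm, "activity_confusion"))
  cs <- colSums(cm)
  denom <- ifelse(cs == 0, 1, cs)
  eta <- sweep(unclass(cm) * 1.0, 2, denom, "/")
  structure(eta, class = c("confusion_ratios", "matrix", "array"))
}

#' Per-activity confusing sets at a ratio threshold
#'
#' Activity `L_B` is a confusing activity of `L_A` when `L_B != L_A` and
#' eta(L_B, L_A) >= theta. Every activity with a non-empty confusing set
#' triggers a second-level classifier in the hierarchical recognizer.
#'
#' @param cm An `activity_confusion` matrix.
#' @param theta Confusion threshold in (0, 1]. Default 0.01, the empirical
#'   working point.
#' @return An object of class `confusing_set_map`: a named list mapping
#'   every activity to a (possibly empty) character vector of its
#'   confusers, with attribute `theta`.
#' @export
confusing_sets <- function(cm, theta = 0.01) {
  stopifnot(inherits(cm, "activity_confusion"))
  if (!is.numeric(theta) || length(theta) != 1 ||
      !is.finite(theta) || theta <= 0 || theta > 1) {
    stop("theta must be a single value in (0, 1]", call. = FALSE)
  }
  eta <- confusion_ratios(cm)
  L <- colnames(cm)
  sets <- lapply(seq_along(L), function(i) {
    hits <- which(eta[, i] >= theta)
    setdiff(L[hits], L[i])
  })
  names(sets) <- L
  structure(sets, theta = theta, class = "confusing_set_map")
}

#' @export
print.confusing_set_map <- function(x, ...) {
  cat(sprintf("confusing_set_map (theta = %g):\n", attr(x, "theta")))
  for (a in names(x)) {
    cat(sprintf("  S(%s) = {%s}\n", a, paste(x[[a]], collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a labeled activity matrix as TSV
#'
#' The first row and first column carry activity names; suitable for both
#' integer confusion-index matrices and real-valued ratio matrices.
#'
#' @param m Matrix with identical row and column activity names.
#' @param path File path.
#' @return `write_confusion_tsv`: `path` invisibly. `read_confusion_tsv`:
#'   an `activity_confusion` when all entries are whole numbers, otherwise
#'   a plain labeled numeric matrix.
#' @export
write_confusion_tsv <- function(m, path) {
  df <- data.frame(activity = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_tsv
#' @export
read_confusion_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix file must have identical row and column activity names",
         call. = FALSE)
  }
  if (all(m == round(m))) new_activity_confusion(m)
  else structure(m, class = c("confusion_ratios", "matrix", "array"))
}

#' Packaged UCI-HAR activity confusion matrix
#'
#' A reference activity confusion index matrix for the six UCI-HAR
#' activities, computed by k-means partitioning (k = 6) of the 7352
#' training windows of the benchmark. Ships with the package so confusing
#' sets and hierarchy construction can be exercised without downloading
#' the benchmark itself.
#'
#' @return An `activity_confusion` over walking, go-upstairs,
#'   go-downstairs, sitting, standing, lying.
#' @examples
#' cm <- ucihar_confusion_fixture()
#' confusing_sets(cm, theta = 0.03)
#' @export
ucihar_confusion_fixture <- function() {
  read_confusion_tsv(system.file("extdata", "ucihar_activity_confusion.tsv",
                                 package = "harclust", mustWork = TRUE))
}
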