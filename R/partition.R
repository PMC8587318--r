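#' Clustering specification
#'
#' Configures the unsupervised partition step that drives confusion
#' analysis. The cluster count is expressed relative to the number of
#' predefined activities: `cluster_count_offset = 0` gives k = |L| (the
#' default working point), -1 gives |L| - 1, and so on.
#'
#' @param algorithm One of `"kmeans"`, `"kmedoids"`, `"agglomerative"`.
#' @param metric One of `"euclidean"`, `"cosine"`, `"correlation"`. The
#'   agglomerative back end uses Ward linkage, which is defined for
#'   Euclidean geometry only; requesting it with another metric is an
#'   error rather than a silent substitution.
#' @param cluster_count_offset Integer added to |L| to obtain k.
#' @param seed Integer seed controlling k-means/k-medoids initialization.
#' @param max_iterations Positive integer iteration cap for k-means.
#' @param n_restarts Number of random restarts for k-means (best
#'   within-cluster sum of squares wins).
#' @param scale If `TRUE`, z-score the feature columns before clustering.
#'   Off by default: published HAR feature tables are typically already
#'   normalized.
#' @return An object of class `partition_spec`.
#' @export
partition_spec <- function(algorithm = c("kmeans", "kmedoids", "agglomerative"),
                           metric = c("euclidean", "cosine", "correlation"),
                           cluster_count_offset = 0L,
                           seed = 1L,
                           max_iterations = 100L,
                           n_restarts = 10L,
                           scale = FALSE) {
  algorithm <- match.arg(algorithm)
  metric <- match.arg(metric)
  if (algorithm == "agglomerative" && metric != "euclidean") {
    stop("Ward agglomerative clustering is defined for the euclidean ",
         "metric only; got metric = '", metric, "'", call. = FALSE)
  }
  stopifnot(length(cluster_count_offset) == 1,
            cluster_count_offset == as.integer(cluster_count_offset),
            max_iterations >= 1, n_restarts >= 1)
  structure(
    list(algorithm = algorithm, metric = metric,
         cluster_count_offset = as.integer(cluster_count_offset),
         seed = as.integer(seed),
         max_iterations = as.integer(max_iterations),
         n_restarts = as.integer(n_restarts),
         scale = isTRUE(scale)),
    class = "partition_spec"
  )
}

# Metric-specific row transform under which Euclidean k-means is equivalent
# to the requested similarity: cosine = row-normalize; correlation =
# row-center then row-normalize (the spherical k-means equivalence).
transform_rows <- function(x, metric) {
  if (metric == "euclidean") return(x)
  if (metric == "correlation") {
    x <- x - rowMeans(x)
  }
  nrm <- sqrt(rowSums(x^2))
  bad <- which(nrm == 0)
  if (length(bad) > 0) {
    stop(sprintf("metric '%s' undefined for constant-valued sample row %d",
                 metric, bad[1]), call. = FALSE)
  }
  x / nrm
}

# Pairwise dissimilarity for the medoid and linkage back ends.
metric_dist <- function(x, metric) {
  switch(metric,
    euclidean = stats::dist(x),
    # after the row transform, squared Euclidean distance is an affine
    # function of cosine / correlation similarity; use it directly so that
    # medoid choice matches the similarity ordering
    cosine = stats::dist(transform_rows(x, "cosine")),
    correlation = stats::dist(transform_rows(x, "correlation"))
  )
}

#' Partition a feature matrix into k clusters
#'
#' Runs the configured clustering algorithm with k = |L| +
#' `cluster_count_offset`. k-means uses k-means++ seeding with
#' `n_restarts` seeded restarts, keeping the solution with the lowest
#' within-cluster sum of squares; empty clusters (possible in degenerate
#' geometries) are repaired by reseeding a vacant cluster with the sample
#' farthest from its assigned centroid, so the returned partition always
#' has exactly k non-empty groups when k distinct rows exist. For k-means
#' the returned partition also records `objective` (final within-cluster
#' sum of squares) and `initial_objective` (the same quantity at the
#' winning restart's initial centers).
#'
#' @param features Numeric sample-by-feature matrix with no missing values.
#' @param spec A [partition_spec()].
#' @param k Number of clusters. Callers working from a labeled dataset
#'   normally pass `length(label_set) + spec$cluster_count_offset`;
#'   [partition_dataset()] does this for you.
#' @return An object of class `cluster_partition`: list with `assignment`
#'   (integer vector in 1..k, one entry per row), `k`, and `repaired`
#'   (logical, `TRUE` when empty-cluster repair ran).
#' @seealso [partition_dataset()]
#' @export
partition <- function(features, spec, k) {
  if (is.data.frame(features)) features <- as.matrix(features)
  stopifnot(inherits(spec, "partition_spec"), is.matrix(features))
  if (anyNA(features) || any(!is.finite(features))) {
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  }
  n <- nrow(features)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) {
    stop(sprintf("k = %d exceeds the number of samples (%d)", k, n),
         call. = FALSE)
  }
  if (spec$scale) {
    features <- scale(features)
    features[, attr(features, "scaled:scale") == 0] <- 0
  }
  if (k == 1L) {
    return(new_cluster_partition(rep(1L, n), 1L))
  }
  assignment <- switch(spec$algorithm,
    kmeans = partition_kmeans(features, spec, k),
    kmedoids = partition_kmedoids(features, spec, k),
    agglomerative = partition_ward(features, k)
  )
  assignment
}

new_cluster_partition <- function(assignment, k, repaired = FALSE) {
  structure(list(assignment = as.integer(assignment), k = as.integer(k),
                 repaired = repaired),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition: %d samples in %d clusters\n",
              length(x$assignment), x$k))
  print(table(cluster = x$assignment))
  invisible(x)
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance from the nearest chosen one
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) == 0) {
      stop("fewer distinct rows than clusters requested", call. = FALSE)
    }
    i <- sample.int(n, 1, prob = d2 / sum(d2))
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

wss_at <- function(x, centers, assignment) {
  sum((x - centers[assignment, , drop = FALSE])^2)
}

nearest_center <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

partition_kmeans <- function(features, spec, k) {
  x <- transform_rows(features, spec$metric)
  best <- with_seed(spec$seed, {
    out <- NULL
    for (r in seq_len(spec$n_restarts)) {
      cen <- kmeanspp_centers(x, k)
      w0 <- wss_at(x, cen, nearest_center(x, cen))
      fit <- tryCatch(
        stats::kmeans(x, centers = cen, iter.max = spec$max_iterations),
        error = function(e)
          tryCatch(stats::kmeans(x, centers = cen,
                                 iter.max = spec$max_iterations,
                                 algorithm = "Lloyd"),
                   error = function(e2) NULL))
      if (is.null(fit)) next
      if (is.null(out) || fit$tot.withinss < out$fit$tot.withinss) {
        out <- list(fit = fit, initial_objective = w0)
      }
    }
    if (is.null(out)) {
      stop("k-means failed on every restart; check for degenerate input",
           call. = FALSE)
    }
    out
  })
  fit <- best$fit
  assignment <- fit$cluster
  repaired <- FALSE
  present <- tabulate(assignment, nbins = k)
  while (any(present == 0L)) {
    repaired <- TRUE
    empty <- which(present == 0L)[1]
    # reseed the vacant cluster with the sample farthest from its centroid
    centers <- fit$centers
    d2 <- rowSums((x - centers[assignment, , drop = FALSE])^2)
    donor_ok <- present[assignment] > 1L
    cand <- which(donor_ok)
    moved <- cand[which.max(d2[cand])]
    assignment[moved] <- empty
    message(sprintf(
      "empty-cluster repair: sample %d reassigned to vacant cluster %d",
      moved, empty))
    present <- tabulate(assignment, nbins = k)
  }
  part <- new_cluster_partition(assignment, k, repaired)
  part$objective <- fit$tot.withinss
  part$initial_objective <- best$initial_objective
  part
}

partition_kmedoids <- function(features, spec, k) {
  d <- metric_dist(features, spec$metric)
  fit <- with_seed(spec$seed,
                   cluster::pam(d, k = k, diss = TRUE, cluster.only = FALSE))
  new_cluster_partition(fit$clustering, k)
}

partition_ward <- function(features, k) {
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  new_cluster_partition(stats::cutree(hc, k = k), k)
}

#' Partition a labeled dataset
#'
#' Convenience wrapper: k is derived from the dataset's label set and the
#' spec's `cluster_count_offset` (k = |L| + offset).
#'
#' @param dataset A [labeled_dataset()].
#' @param spec A [partition_spec()].
#' @return A `cluster_partition` over the dataset's samples.
#' @export
partition_dataset <- function(dataset, spec) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  k <- length(dataset$label_set) + spec$cluster_count_offset
  if (k < 1) {
    stop(sprintf("cluster_count_offset %d yields k = %d < 1",
                 spec$cluster_count_offset, k), call. = FALSE)
  }
  partition(dataset$features, spec, k = k)
}

#' Write a partition as two-column delimited text
#'
#' @param part A `cluster_partition`.
#' @param path Output file; tab-separated with a header row
#'   (`sample_index`, `cluster_id`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "cluster_partition"))
  utils::write.table(
    data.frame(sample_index = seq_along(part$assignment),
               cluster_id = part$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a pinned RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
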