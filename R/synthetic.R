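#' Specification for the planted-group synthetic benchmark
#'
#' Generates labeled Gaussian feature data emulating the situation the
#' framework targets: activities fall into groups (e.g. a dynamic group
#' walking / go-upstairs / go-downstairs and a static group sitting /
#' standing / lying) whose members have similar sensor readings, while the
#' groups themselves are well separated. Class-conditional features are
#' spherical Gaussians; class means are laid out deterministically so that
#' mean distances inside a group equal `within_group_separation * noise_sd`
#' and distances between group centers equal
#' `between_group_separation * noise_sd`.
#'
#' The mean layout uses a fixed simplex construction: group centers sit on
#' a regular simplex spanning the first `G - 1` feature dimensions, class
#' offsets within each group on a regular simplex spanning the next
#' `max(group size) - 1` dimensions, and any remaining dimensions carry
#' pure noise. The default `dim = 6` therefore gives (for two groups of
#' three) one group axis, two within-group simplex dimensions and three
#' noise dimensions.
#'
#' @param groups List of character vectors partitioning the activity list
#'   into disjoint groups.
#' @param n_per_class Training samples per activity.
#' @param n_test_per_class Test samples per activity (drawn independently).
#' @param dim Feature count; must be at least
#'   `(G - 1) + (max group size - 1)`.
#' @param within_group_separation Distance between class means inside a
#'   group, in units of `noise_sd`.
#' @param between_group_separation Distance between group centers, same
#'   units; must exceed `within_group_separation` for a valid confusable
#'   design.
#' @param noise_sd Standard deviation of the isotropic feature noise.
#' @param entangle_pair If `TRUE`, two extra feature dimensions are
#'   appended in which the first two activities of the first group share a
#'   strong common latent factor and differ only by a mean offset lying in
#'   a non-eigen direction of the induced covariance. A
#'   diagonal-covariance naive Bayes then confuses the pair while a linear
#'   decision rule separates it — creating headroom for second-level
#'   routing gains that purely spherical classes do not leave.
#' @param seed Integer seed; a fixed seed reproduces the draw exactly.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(groups = list(
                             dynamic = c("walking", "go-upstairs",
                                         "go-downstairs"),
                             static = c("sitting", "standing", "lying")),
                           n_per_class = 300L,
                           n_test_per_class = 150L,
                           dim = 6L,
                           within_group_separation = 1,
                           between_group_separation = 8,
                           noise_sd = 1,
                           entangle_pair = FALSE,
                           seed = 1L) {
  if (!is.list(groups) || length(groups) < 1) {
    stop("`groups` must be a non-empty list of activity vectors",
         call. = FALSE)
  }
  acts <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(acts)) {
    stop("groups must be disjoint: each activity appears exactly once",
         call. = FALSE)
  }
  if (length(acts) < 2) stop("need at least two activities", call. = FALSE)
  if (within_group_separation < 0 || between_group_separation < 0 ||
      noise_sd <= 0) {
    stop("separations must be nonnegative and noise_sd positive",
         call. = FALSE)
  }
  if (length(groups) > 1 &&
      between_group_separation <= within_group_separation) {
    stop("between_group_separation must exceed within_group_separation ",
         "for a confusable design", call. = FALSE)
  }
  structural <- (length(groups) - 1) + (max(lengths(groups)) - 1)
  if (dim < max(structural, 1)) {
    stop(sprintf("dim = %d too small; the mean layout needs %d dimensions",
                 dim, structural), call. = FALSE)
  }
  stopifnot(n_per_class >= 1, n_test_per_class >= 1)
  structure(
    list(groups = groups, n_per_class = as.integer(n_per_class),
         n_test_per_class = as.integer(n_test_per_class),
         dim = as.integer(dim),
         within_group_separation = within_group_separation,
         between_group_separation = between_group_separation,
         noise_sd = noise_sd, entangle_pair = isTRUE(entangle_pair),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# m points of a regular simplex with pairwise distance d, in m-1 columns
# (deterministic: centered identity vertices rotated into their span by QR)
simplex_coords <- function(m, d) {
  if (m == 1) return(matrix(0, 1, 0))
  v <- (diag(m) - 1 / m) * d / sqrt(2)
  q <- qr.Q(qr(t(v)))[, seq_len(m - 1), drop = FALSE]
  v %*% q
}

# activity -> mean vector matrix (activities x dim), deterministic layout
planted_means <- function(spec) {
  G <- length(spec$groups)
  acts <- unlist(spec$groups, use.names = FALSE)
  centers <- simplex_coords(G, spec$between_group_separation * spec$noise_sd)
  maxm <- max(lengths(spec$groups))
  mu <- matrix(0, length(acts), spec$dim,
               dimnames = list(acts, paste0("f", seq_len(spec$dim))))
  g_dims <- seq_len(G - 1)
  w_dims <- (G - 1) + seq_len(maxm - 1)
  row <- 1
  for (g in seq_len(G)) {
    members <- spec$groups[[g]]
    offs <- simplex_coords(length(members),
                           spec$within_group_separation * spec$noise_sd)
    for (j in seq_along(members)) {
      if (G > 1) mu[row, g_dims] <- centers[g, ]
      if (length(members) > 1 && ncol(offs) > 0) {
        mu[row, w_dims[seq_len(ncol(offs))]] <- offs[j, ]
      }
      row <- row + 1
    }
  }
  mu
}

# parameters of the entangled-pair block (two appended dimensions)
entangle_params <- function() {
  list(latent_sd = 1, noise_sd = 0.3, shift = 1.2)
}

draw_block <- function(spec, n_each, mu) {
  acts <- rownames(mu)
  n <- n_each * length(acts)
  x <- matrix(stats::rnorm(n * spec$dim, sd = spec$noise_sd), n, spec$dim)
  labels <- rep(acts, each = n_each)
  for (a in acts) {
    idx <- which(labels == a)
    x[idx, ] <- sweep(x[idx, , drop = FALSE], 2, mu[a, ], "+")
  }
  if (spec$entangle_pair) {
    ep <- entangle_params()
    pair <- spec$groups[[1]][1:2]
    extra <- matrix(stats::rnorm(n * 2), n, 2)
    in_pair <- labels %in% pair
    z <- stats::rnorm(sum(in_pair), sd = ep$latent_sd)
    e <- matrix(stats::rnorm(sum(in_pair) * 2, sd = ep$noise_sd),
                ncol = 2)
    extra[in_pair, ] <- cbind(z + e[, 1], z + e[, 2])
    extra[labels == pair[2], 1] <-
      extra[labels == pair[2], 1] + ep$shift
    x <- cbind(x, extra)
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  labeled_dataset(x, labels, label_set = acts)
}

#' Generate a planted-group benchmark draw
#'
#' Draws independent train and test sets from the class-conditional
#' Gaussians configured by the spec. Fixed seed implies an identical
#' draw.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `train` and `test`, both
#'   [labeled_dataset()]s over the spec's activities (in group order), and
#'   `means`, the planted activity-by-dimension mean matrix.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mu <- planted_means(spec)
  with_seed(spec$seed, {
    train <- draw_block(spec, spec$n_per_class, mu)
    test <- draw_block(spec, spec$n_test_per_class, mu)
    list(train = train, test = test, means = mu)
  })
}

#' Planted ground-truth confusing sets
#'
#' The confusing-set map the framework is expected to recover under
#' successful clustering: each activity maps to the other members of its
#' planted group.
#'
#' @param spec A [synthetic_spec()].
#' @return A `confusing_set_map` (with `theta = NA`, since it is ground
#'   truth rather than a thresholded estimate).
#' @export
planted_confusion_sets <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  acts <- unlist(spec$groups, use.names = FALSE)
  sets <- lapply(acts, function(a) {
    g <- spec$groups[[which(vapply(spec$groups, function(g) a %in% g,
                                   logical(1)))[1]]]
    setdiff(g, a)
  })
  names(sets) <- acts
  structure(sets, theta = NA_real_, class = "confusing_set_map")
}
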