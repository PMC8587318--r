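# Independent oracles and small data builders shared across test files.
# Oracles deliberately use plain loops, not the package's vectorized paths.

# brute-force activity confusion matrix: for each cluster find the majority
# by direct counting (ties -> earliest label in the ordered set), then walk
# the samples one by one and increment cells
brute_force_cm <- function(dataset, part) {
  L <- dataset$label_set
  labs <- as.character(dataset$labels)
  maj <- character(max(part$assignment))
  for (c_id in sort(unique(part$assignment))) {
    members <- labs[part$assignment == c_id]
    best <- L[1]; best_n <- -1
    for (a in L) {
      n_a <- sum(members == a)
      if (n_a > best_n) { best <- a; best_n <- n_a }
    }
    maj[c_id] <- best
  }
  cm <- matrix(0L, length(L), length(L), dimnames = list(L, L))
  for (i in seq_along(labs)) {
    tgt <- maj[part$assignment[i]]
    cm[labs[i], tgt] <- cm[labs[i], tgt] + 1L
  }
  cm
}

# manual two-step routing: top-level model, then the second-level model of
# the top label when one exists
manual_route <- function(model, newdata) {
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    row <- newdata[i, , drop = FALSE]
    top <- as.character(predict(model$top_model, row))
    out[i] <- if (top %in% names(model$second_models)) {
      as.character(predict(model$second_models[[top]], row))
    } else top
  }
  out
}

# k well-separated Gaussian blobs; returns dataset plus the planted
# assignment
make_blobs <- function(k = 3, n_per = 20, d = 4, sep = 50, sd = 1,
                       seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, d)
  for (j in seq_len(k)) centers[j, ((j - 1) %% d) + 1] <- (j - 1) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[j, ], n_per, d, byrow = TRUE)
  }))
  list(x = x, planted = rep(seq_len(k), each = n_per))
}

# adjusted agreement via best bijective relabeling (exhaustive over
# permutations; fine for k <= 5)
best_relabel_agreement <- function(a, b) {
  k <- max(a, b)
  perms <- perms_of(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(p[a] == b))
  best
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# small random labeled dataset with a random partition, for property tests
random_case <- function(seed, max_n = 200, n_labels = 4, k = 5) {
  set.seed(seed)
  n <- sample(20:max_n, 1)
  L <- paste0("act", seq_len(n_labels))
  d <- labeled_dataset(matrix(rnorm(n * 3), n, 3),
                       sample(L, n, replace = TRUE), label_set = L)
  part <- structure(
    list(assignment = sample(seq_len(k), n, replace = TRUE), k = k,
         repaired = FALSE),
    class = "cluster_partition")
  list(dataset = d, part = part)
}

# labeled two-class data with overlapping classes, for routing tests
make_overlap_dataset <- function(seed = 1, n_per = 40) {
  set.seed(seed)
  L <- c("a", "b", "c")
  x <- rbind(matrix(rnorm(n_per * 2, 0), n_per, 2),
             matrix(rnorm(n_per * 2, 1), n_per, 2),
             matrix(rnorm(n_per * 2, 8), n_per, 2))
  labeled_dataset(x, rep(L, each = n_per), label_set = L)
}

strict_set_match <- function(sets, truth) {
  all(vapply(names(truth), function(k) setequal(sets[[k]], truth[[k]]),
             logical(1)))
}
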