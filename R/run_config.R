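#' Execute a configured run and write its artifacts
#'
#' The single entry point behind the command-line interface. A
#' configuration is a plain named list (typically read from YAML with
#' [read_run_config()]); one top-level `seed` flows into every stochastic
#' component via fixed offsets, so a single integer reproduces a whole
#' run. A config echo is written to the output directory; re-running from
#' the echo reproduces the outputs.
#'
#' Recognized fields (all optional unless an action needs them):
#' \describe{
#'   \item{action}{one of `simulate`, `analyze-confusion`, `train`,
#'     `predict`, `evaluate`, `sweep`}
#'   \item{out_dir}{output directory}
#'   \item{seed}{integer master seed (default 1)}
#'   \item{train, test}{feature-table paths (delimited dialect) or layout
#'     lists with the [dataset_layout()] fields}
#'   \item{columns}{feature-subset selector passed to [load_dataset()]}
#'   \item{confusion_matrix}{path to a precomputed labeled confusion TSV
#'     (lets `analyze-confusion` run without re-clustering)}
#'   \item{theta}{confusion threshold (default 0.01)}
#'   \item{partition}{list of [partition_spec()] fields}
#'   \item{top, second}{lists of [classifier_spec()] fields}
#'   \item{synthetic}{list of [synthetic_spec()] fields (for `simulate`)}
#'   \item{model_dir}{model bundle directory (for `predict` / `evaluate`)}
#'   \item{sweep_axis, sweep_values}{sweep request (for `sweep`)}
#' }
#'
#' @param config Named list as above.
#' @return Invisibly, a list of the objects the action produced; artifacts
#'   are written under `out_dir`.
#' @export
run_config <- function(config) {
  action <- config$action %||% stop("config must name an `action`",
                                    call. = FALSE)
  actions <- c("simulate", "analyze-confusion", "train", "predict",
               "evaluate", "sweep")
  if (!action %in% actions) {
    stop(sprintf("unknown action '%s' (expected one of %s)", action,
                 paste(actions, collapse = ", ")), call. = FALSE)
  }
  out_dir <- config$out_dir %||% stop("config must name an `out_dir`",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
  seed <- as.integer(config$seed %||% 1L)

  switch(action,
    simulate = cfg_simulate(config, out_dir, seed),
    `analyze-confusion` = cfg_analyze(config, out_dir, seed),
    train = cfg_train(config, out_dir, seed),
    predict = cfg_predict(config, out_dir),
    evaluate = cfg_evaluate(config, out_dir),
    sweep = cfg_sweep(config, out_dir, seed)
  )
}

#' Read a YAML run configuration
#' @param path YAML file with the fields documented in [run_config()].
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

cfg_layout <- function(entry) {
  if (is.character(entry)) {
    dataset_layout("delimited", features_path = entry)
  } else {
    do.call(dataset_layout, entry)
  }
}

cfg_load <- function(config, which) {
  entry <- config[[which]] %||%
    stop(sprintf("action '%s' needs a `%s` dataset", config$action, which),
         call. = FALSE)
  load_dataset(cfg_layout(entry), columns = config$columns)
}

cfg_partition_spec <- function(config, seed) {
  p <- config$partition %||% list()
  partition_spec(
    algorithm = p$algorithm %||% "kmeans",
    metric = p$metric %||% "euclidean",
    cluster_count_offset = p$cluster_count_offset %||% 0L,
    seed = p$seed %||% seed,
    max_iterations = p$max_iterations %||% 100L,
    n_restarts = p$n_restarts %||% 10L,
    scale = p$scale %||% FALSE)
}

cfg_classifier_spec <- function(entry, seed) {
  e <- entry %||% list()
  classifier_spec(
    family = e$family %||% "naive_bayes",
    neighbors = e$neighbors %||% 1L,
    cost = e$cost %||% 1,
    min_split = e$min_split %||% 2L,
    complexity = e$complexity %||% 0,
    seed = e$seed %||% seed)
}

cfg_simulate <- function(config, out_dir, seed) {
  s <- config$synthetic %||% list()
  if (is.null(s$seed)) s$seed <- seed
  s <- s[intersect(names(s), names(formals(synthetic_spec)))]
  spec <- do.call(synthetic_spec, s)
  draw <- generate(spec)
  write_dataset(draw$train, file.path(out_dir, "train.tsv"))
  write_dataset(draw$test, file.path(out_dir, "test.tsv"))
  write_confusing_sets_tsv(planted_confusion_sets(spec),
                           file.path(out_dir, "planted_sets.tsv"))
  message(sprintf("simulate: wrote %d train / %d test samples to %s",
                  n_samples(draw$train), n_samples(draw$test), out_dir))
  invisible(draw)
}

cfg_analyze <- function(config, out_dir, seed) {
  theta <- config$theta %||% 0.01
  if (!is.null(config$confusion_matrix)) {
    cm <- read_confusion_tsv(config$confusion_matrix)
    if (!inherits(cm, "activity_confusion")) {
      stop("`confusion_matrix` must be an integer confusion-index matrix",
           call. = FALSE)
    }
  } else {
    train <- cfg_load(config, "train")
    part <- partition_dataset(train, cfg_partition_spec(config, seed))
    write_partition(part, file.path(out_dir, "partition.tsv"))
    cm <- activity_confusion_matrix(train, part)
  }
  eta <- confusion_ratios(cm)
  sets <- confusing_sets(cm, theta)
  write_confusion_tsv(cm, file.path(out_dir, "confusion_matrix.tsv"))
  write_confusion_tsv(eta, file.path(out_dir, "confusion_ratios.tsv"))
  write_confusing_sets_tsv(sets, file.path(out_dir, "confusing_sets.tsv"))
  message(sprintf("analyze-confusion: theta = %g, %d activities with confusers",
                  theta, sum(lengths(sets) > 0)))
  invisible(list(cm = cm, ratios = eta, sets = sets))
}

cfg_train <- function(config, out_dir, seed) {
  train <- cfg_load(config, "train")
  model <- fit_pipeline(
    train,
    part_spec = cfg_partition_spec(config, seed),
    theta = config$theta %||% 0.01,
    top_spec = cfg_classifier_spec(config$top, seed + 1L),
    second_spec = cfg_classifier_spec(config$second %||% config$top,
                                      seed + 2L))
  write_model_bundle(model, file.path(out_dir, "model"))
  message(sprintf("train: %d second-level model(s) for {%s}",
                  length(model$second_models),
                  paste(names(model$second_models), collapse = ", ")))
  invisible(model)
}

cfg_predict <- function(config, out_dir) {
  model <- read_model_bundle(config$model_dir %||%
    stop("predict needs `model_dir`", call. = FALSE))
  test <- cfg_load(config, "test")
  pred <- predict(model, test$features)
  utils::write.table(pred, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pred)
}

cfg_evaluate <- function(config, out_dir) {
  model <- read_model_bundle(config$model_dir %||%
    stop("evaluate needs `model_dir`", call. = FALSE))
  test <- cfg_load(config, "test")
  report <- evaluate(model, test)
  write_metrics_tsv(stats::setNames(
    list(report), paste(model$top_spec$family, model$second_spec$family,
                        sep = "-")),
    file.path(out_dir, "metrics.tsv"))
  write_confusion_tsv(report$per_class_confusion,
                      file.path(out_dir, "prediction_confusion.tsv"))
  message(sprintf("evaluate: accuracy %.4f, F1 %.4f",
                  report$accuracy, report$f1))
  invisible(report)
}

cfg_sweep <- function(config, out_dir, seed) {
  axis <- config$sweep_axis %||% stop("sweep needs `sweep_axis`",
                                      call. = FALSE)
  values <- config$sweep_values %||% stop("sweep needs `sweep_values`",
                                          call. = FALSE)
  train <- cfg_load(config, "train")
  test <- cfg_load(config, "test")
  base <- list(part_spec = cfg_partition_spec(config, seed),
               theta = config$theta %||% 0.01,
               top_spec = cfg_classifier_spec(config$top, seed + 1L),
               second_spec = cfg_classifier_spec(
                 config$second %||% config$top, seed + 2L))
  res <- run_sweep(train, test, base, axis, values)
  utils::write.table(res$metrics, file.path(out_dir, "sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
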