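#' Default UCI-HAR activity key
#'
#' Maps the benchmark's integer label codes to activity names:
#' 1 walking, 2 go-upstairs, 3 go-downstairs, 4 sitting, 5 standing,
#' 6 lying.
#'
#' @return Named character vector (names are the integer codes).
#' @export
ucihar_activity_key <- function() {
  c(`1` = "walking", `2` = "go-upstairs", `3` = "go-downstairs",
    `4` = "sitting", `5` = "standing", `6` = "lying")
}

# declared sensor-subset widths for the 561-feature UCI-HAR table
ucihar_subset_widths <- c(accelerometer = 348L, gyroscope = 211L,
                          combined = 561L)

#' Describe where a feature table lives on disk
#'
#' Two dialects are supported. `"delimited"`: one delimited text file with
#' the label in a named column (default `label`), every other column a
#' numeric feature. `"ucihar"`: the benchmark layout — a
#' whitespace-separated feature matrix file, a separate integer label
#' file, an optional feature-name file, and an integer-to-activity key.
#'
#' @param kind `"delimited"` or `"ucihar"`.
#' @param features_path Feature (or combined) file path.
#' @param labels_path Label file path (ucihar only).
#' @param feature_names_path Optional feature-name list (ucihar only; each
#'   line `index name`).
#' @param delimiter Field delimiter for the delimited dialect (default
#'   tab; `"auto"` lets the reader sniff).
#' @param label_column Label column name for the delimited dialect.
#' @param label_key Named character vector mapping integer codes to
#'   activity names (ucihar only); defaults to [ucihar_activity_key()].
#' @return An object of class `dataset_layout`.
#' @export
dataset_layout <- function(kind = c("delimited", "ucihar"),
                           features_path,
                           labels_path = NULL,
                           feature_names_path = NULL,
                           delimiter = "auto",
                           label_column = "label",
                           label_key = ucihar_activity_key()) {
  kind <- match.arg(kind)
  if (kind == "ucihar" && is.null(labels_path)) {
    stop("ucihar layout needs a separate `labels_path`", call. = FALSE)
  }
  structure(
    list(kind = kind, features_path = features_path,
         labels_path = labels_path,
         feature_names_path = feature_names_path, delimiter = delimiter,
         label_column = label_column, label_key = label_key),
    class = "dataset_layout"
  )
}

#' Load a labeled feature table
#'
#' @param layout A [dataset_layout()].
#' @param columns Optional feature subset: an integer/character column
#'   selector, or for the ucihar dialect one of `"accelerometer"`,
#'   `"gyroscope"`, `"combined"` (name-pattern selection against the
#'   feature-name file, validated against the declared widths 348 / 211 /
#'   561 of the benchmark).
#' @return A [labeled_dataset()]. For the ucihar dialect the ordered label
#'   set follows the integer key; for delimited tables it is the sorted
#'   distinct labels.
#' @export
load_dataset <- function(layout, columns = NULL) {
  stopifnot(inherits(layout, "dataset_layout"))
  if (layout$kind == "delimited") {
    load_delimited(layout, columns)
  } else {
    load_ucihar(layout, columns)
  }
}

load_delimited <- function(layout, columns) {
  sep <- if (identical(layout$delimiter, "auto")) "auto" else layout$delimiter
  dt <- data.table::fread(layout$features_path, sep = sep,
                          header = TRUE, data.table = FALSE)
  if (!layout$label_column %in% colnames(dt)) {
    stop(sprintf("label column '%s' not found in %s", layout$label_column,
                 layout$features_path), call. = FALSE)
  }
  labels <- as.character(dt[[layout$label_column]])
  x <- as.matrix(dt[, setdiff(colnames(dt), layout$label_column),
                    drop = FALSE])
  storage.mode(x) <- "double"
  if (!is.null(columns)) x <- x[, columns, drop = FALSE]
  labeled_dataset(x, labels)
}

load_ucihar <- function(layout, columns) {
  x <- as.matrix(data.table::fread(layout$features_path, header = FALSE,
                                   data.table = FALSE))
  storage.mode(x) <- "double"
  codes <- scan(layout$labels_path, what = integer(), quiet = TRUE)
  if (length(codes) != nrow(x)) {
    stop(sprintf("feature rows (%d) and labels (%d) differ",
                 nrow(x), length(codes)), call. = FALSE)
  }
  key <- layout$label_key
  unknown <- which(!as.character(codes) %in% names(key))
  if (length(unknown) > 0) {
    stop(sprintf("unknown label code %s at line %d of %s",
                 codes[unknown[1]], unknown[1], layout$labels_path),
         call. = FALSE)
  }
  labels <- unname(key[as.character(codes)])
  if (!is.null(layout$feature_names_path)) {
    nm <- utils::read.table(layout$feature_names_path,
                            stringsAsFactors = FALSE)
    colnames(x) <- make.unique(nm[[ncol(nm)]])
  }
  if (!is.null(columns)) {
    if (is.character(columns) && length(columns) == 1 &&
        columns %in% names(ucihar_subset_widths)) {
      x <- x[, ucihar_sensor_columns(colnames(x), columns), drop = FALSE]
    } else {
      x <- x[, columns, drop = FALSE]
    }
  }
  labeled_dataset(x, labels, label_set = unname(key))
}

# name-pattern sensor-subset selection for the 561-feature table:
# accelerometer = features derived from Acc signals (and not Gyro),
# gyroscope = features derived from Gyro signals (and not Acc),
# combined = everything. Widths are validated against the declared
# 348 / 211 / 561 counts when the table is full width.
ucihar_sensor_columns <- function(feature_names, subset) {
  if (is.null(feature_names)) {
    stop("sensor-subset selection needs a feature-name file", call. = FALSE)
  }
  acc <- grepl("Acc", feature_names) & !grepl("Gyro", feature_names)
  gyro <- grepl("Gyro", feature_names) & !grepl("Acc", feature_names)
  idx <- switch(subset,
    accelerometer = which(acc),
    gyroscope = which(gyro),
    combined = seq_along(feature_names)
  )
  if (length(feature_names) == ucihar_subset_widths[["combined"]] &&
      length(idx) != ucihar_subset_widths[[subset]]) {
    warning(sprintf(
      "sensor subset '%s' selected %d columns; the benchmark declares %d",
      subset, length(idx), ucihar_subset_widths[[subset]]), call. = FALSE)
  }
  idx
}

#' Write a labeled dataset as a delimited feature table
#'
#' Round-trips with the delimited dialect of [load_dataset()]: features in
#' named numeric columns plus one label column.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output file (tab-separated, header included).
#' @param label_column Name of the label column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, label_column = "label") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  x <- dataset$features
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(x, check.names = FALSE)
  df[[label_column]] <- as.character(dataset$labels)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write confusing sets as labeled TSV
#'
#' Two columns: activity and a comma-joined list of its confusers (empty
#' string for an empty set).
#'
#' @param sets A `confusing_set_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_confusing_sets_tsv <- function(sets, path) {
  stopifnot(inherits(sets, "confusing_set_map"))
  df <- data.frame(
    activity = names(sets),
    confusing_activities = vapply(sets, paste, character(1),
                                  collapse = ","),
    row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
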