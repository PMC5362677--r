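# File formats: pattern CSV (features + label column), interval CSV
# (paired <feat>_lo/<feat>_hi columns, or plain feature columns for crisp
# points), JSON model serialization, and YAML/JSON experiment configs.
# Dialect: comma-separated, UTF-8, "." decimal point, mandatory header;
# unbounded interval ends use the tokens "inf" / "-inf".

MODEL_FORMAT_VERSION <- 1L

parse_numeric_column <- function(col, name, path) {
  if (is.numeric(col)) return(as.numeric(col))
  v <- suppressWarnings(as.numeric(ifelse(
    tolower(trimws(col)) == "inf", Inf,
    ifelse(tolower(trimws(col)) == "-inf", -Inf, col)
  )))
  bad <- which(is.na(v) & !is.na(col))
  if (length(bad)) {
    abort_schema(sprintf("%s: non-numeric value in column '%s', row %d",
                         path, name, bad[1]))
  }
  v
}

#' Read a pattern table from CSV
#'
#' Expects a header row, one numeric column per feature, and a label
#' column (by default named `label`, otherwise the last non-numeric
#' column).  Missing values, non-numeric feature cells and singleton
#' classes are schema errors that name the offending location.
#'
#' @param path CSV file path.
#' @param label_column name of the class-label column.
#' @return a named list of numeric matrices, classes in order of first
#'   appearance, row order preserved.
#' @export
read_pattern_csv <- function(path, label_column = "label") {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    abort_schema(sprintf("%s: missing label column '%s'", path, label_column))
  }
  labels <- as.character(df[[label_column]])
  feats <- setdiff(names(df), label_column)
  if (!length(feats)) abort_schema(sprintf("%s: no feature columns", path))
  X <- matrix(NA_real_, nrow(df), length(feats),
              dimnames = list(NULL, feats))
  for (f in feats) {
    col <- df[[f]]
    na <- which(is.na(col))
    if (length(na)) {
      abort_schema(sprintf("%s: missing value in column '%s', row %d",
                           path, f, na[1]))
    }
    v <- parse_numeric_column(col, f, path)
    if (any(!is.finite(v))) {
      abort_schema(sprintf("%s: non-finite value in feature column '%s'", path, f))
    }
    X[, f] <- v
  }
  if (anyNA(labels) || any(labels == "")) {
    abort_schema(sprintf("%s: empty class label in column '%s'", path, label_column))
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    abort_schema(sprintf("%s: class(es) with fewer than 2 rows: %s", path,
                         paste(names(counts)[counts < 2], collapse = ", ")))
  }
  out <- lapply(unique(labels), function(l) X[labels == l, , drop = FALSE])
  names(out) <- unique(labels)
  out
}

#' Write a pattern table to CSV
#'
#' @param patterns named list of numeric matrices.
#' @param path output CSV path.
#' @param label_column name of the label column to emit.
#' @export
write_pattern_csv <- function(patterns, path, label_column = "label") {
  rows <- lapply(names(patterns), function(l) {
    df <- as.data.frame(as.matrix(patterns[[l]]))
    if (is.null(colnames(patterns[[l]]))) {
      names(df) <- paste0("x", seq_len(ncol(df)))
    }
    df[[label_column]] <- l
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read interval queries from CSV
#'
#' Accepts either paired bound columns `<feat>_lo` / `<feat>_hi` per
#' feature, or plain feature columns, in which case the rows are taken as
#' crisp points (degenerate intervals).  The tokens `inf` and `-inf`
#' denote unbounded interval ends.  A row with `lo > hi` is a validation
#' error naming the row.
#'
#' @param path CSV file path.
#' @return a list with N x n matrices `lower` and `upper` (feature names as
#'   column names) suitable for [predict.ipnn()].
#' @export
read_interval_csv <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- setdiff(names(df), "id")
  lo_cols <- grep("_lo$", cols, value = TRUE)
  if (length(lo_cols)) {
    feats <- sub("_lo$", "", lo_cols)
    hi_cols <- paste0(feats, "_hi")
    missing <- hi_cols[!hi_cols %in% cols]
    if (length(missing)) {
      abort_schema(sprintf("%s: missing bound column(s): %s", path,
                           paste(missing, collapse = ", ")))
    }
    lower <- sapply(seq_along(feats), function(k) {
      parse_numeric_column(df[[lo_cols[k]]], lo_cols[k], path)
    })
    upper <- sapply(seq_along(feats), function(k) {
      parse_numeric_column(df[[hi_cols[k]]], hi_cols[k], path)
    })
    lower <- matrix(lower, nrow(df), dimnames = list(NULL, feats))
    upper <- matrix(upper, nrow(df), dimnames = list(NULL, feats))
    if (anyNA(lower) || anyNA(upper)) {
      abort_schema(sprintf("%s: missing interval bound", path))
    }
    bad <- which(rowSums(lower > upper) > 0)
    if (length(bad)) {
      abort_invalid_interval(sprintf(
        "%s: lower bound exceeds upper bound in row(s) %s", path,
        paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    return(list(lower = lower, upper = upper))
  }
  # crisp points
  X <- sapply(cols, function(f) {
    v <- parse_numeric_column(df[[f]], f, path)
    na <- which(is.na(df[[f]]))
    if (length(na)) {
      abort_schema(sprintf("%s: missing value in column '%s', row %d",
                           path, f, na[1]))
    }
    v
  })
  X <- matrix(X, nrow(df), dimnames = list(NULL, cols))
  list(lower = X, upper = X)
}

#' Write interval queries to CSV
#'
#' @param intervals a list with matrices `lower` and `upper`.
#' @param path output CSV path.
#' @export
write_interval_csv <- function(intervals, path) {
  lower <- as.matrix(intervals$lower)
  upper <- as.matrix(intervals$upper)
  feats <- colnames(lower)
  if (is.null(feats)) feats <- paste0("x", seq_len(ncol(lower)))
  df <- data.frame(row.names = seq_len(nrow(lower)))
  for (k in seq_along(feats)) {
    df[[paste0(feats[k], "_lo")]] <- lower[, k]
    df[[paste0(feats[k], "_hi")]] <- upper[, k]
  }
  for (nm in names(df)) {
    v <- df[[nm]]
    if (any(!is.finite(v))) {
      v <- as.character(v)
      v[v == "Inf"] <- "inf"
      v[v == "-Inf"] <- "-inf"
      df[[nm]] <- v
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a trained model to JSON
#'
#' The model file is self-describing: format version, class labels, pattern
#' matrices, bandwidth vectors with their plug-in traces, modification
#' coefficients, intensity, and prior mode.  [read_ipnn_model()] restores a
#' model that predicts identically.
#'
#' @param model an [ipnn_fit()] model.
#' @param path output path.
#' @export
write_ipnn_model <- function(model, path) {
  stopifnot(inherits(model, "ipnn"))
  payload <- list(
    format = "ipnn-model",
    version = MODEL_FORMAT_VERSION,
    package_version = as.character(utils::packageVersion("ipnn")),
    prior = model$prior,
    c = model$c,
    n = model$n,
    labels = model$labels,
    classes = lapply(model$models, function(dm) {
      list(points = dm$points, h = dm$h, s = dm$s, c = dm$c,
           traces = lapply(dm$traces, function(tr) unclass(tr)))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a model written by [write_ipnn_model()]
#'
#' @param path model JSON path.
#' @return an `"ipnn"` model.
#' @export
read_ipnn_model <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format) || payload$format != "ipnn-model") {
    abort_schema(sprintf("%s: not an ipnn model file", path))
  }
  if (payload$version > MODEL_FORMAT_VERSION) {
    abort_schema(sprintf("%s: model format version %s is newer than supported (%d)",
                         path, payload$version, MODEL_FORMAT_VERSION))
  }
  models <- lapply(payload$labels, function(lab) {
    cls <- payload$classes[[lab]]
    pts <- cls$points
    if (!is.matrix(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
    density_model(pts, h = as.numeric(cls$h), c = cls$c,
                  s = as.numeric(cls$s))
  })
  names(models) <- payload$labels
  out <- ipnn_model(models, prior = payload$prior, c = payload$c)
  out
}

#' Read an experiment configuration from YAML or JSON
#'
#' The file mirrors the arguments of [experiment_config()]:
#' `class_specs` (named list of `means` / `weights`), `m_grid`,
#' `interval_lengths`, and optional `test_per_class`, `repetitions`,
#' `seed`, `c`, `prior`.  Alternatively a top-level `preset` name (with
#' optional overrides `m`, `lengths`, `repetitions`, `seed`) selects a
#' built-in design.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$preset)) {
    args <- raw[names(raw) %in% c("m", "lengths", "repetitions",
                                  "test_per_class", "seed", "c")]
    return(do.call(experiment_preset, c(list(name = raw$preset), args)))
  }
  specs <- lapply(raw$class_specs, function(s) {
    class_spec(do.call(rbind, lapply(s$means, as.numeric)),
               if (is.null(s$weights)) NULL else as.numeric(s$weights))
  })
  args <- list(class_specs = specs,
               m_grid = raw$m_grid,
               interval_lengths = as.numeric(raw$interval_lengths))
  for (f in c("test_per_class", "repetitions", "seed", "c", "prior")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(experiment_config, args)
}
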