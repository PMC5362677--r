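# The interval probabilistic neural network proper: training (one density
# model per class) and the Bayes decision rule for crisp points and interval
# vectors.

TIE_REL_TOL <- 1e-12

#' Interval vector (hyper-rectangular query)
#'
#' An imprecise query item: per-feature bounds
#' \eqn{[\underline{x}_k, \overline{x}_k]} with
#' \eqn{\underline{x}_k \le \overline{x}_k}.  Infinite bounds are allowed;
#' a crisp point is the degenerate case `lower == upper`.
#'
#' @param lower,upper numeric vectors of equal length; `NA` forbidden.
#' @return an object of class `"interval_vector"` with fields `lower` and
#'   `upper`.
#' @export
interval_vector <- function(lower, upper) {
  check_finite_numeric(lower, "lower", allow_infinite = TRUE)
  check_finite_numeric(upper, "upper", allow_infinite = TRUE)
  if (length(lower) != length(upper)) {
    abort_invalid_interval("`lower` and `upper` must have the same length")
  }
  bad <- which(lower > upper)
  if (length(bad)) {
    abort_invalid_interval(sprintf(
      "lower bound exceeds upper bound in dimension(s) %s",
      paste(bad, collapse = ", ")
    ))
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "interval_vector")
}

as_interval_vector <- function(x, n) {
  if (inherits(x, "interval_vector")) {
    iv <- x
  } else if (is.numeric(x) && is.null(dim(x))) {
    iv <- interval_vector(x, x)  # crisp point
  } else if (is.list(x) && !is.null(x$lower) && !is.null(x$upper)) {
    iv <- interval_vector(x$lower, x$upper)
  } else {
    abort_invalid_interval("cannot interpret query as an interval vector")
  }
  if (length(iv$lower) != n) {
    abort_invalid_argument(sprintf("query has %d features, model expects %d",
                                   length(iv$lower), n))
  }
  iv
}

#' @export
print.interval_vector <- function(x, ...) {
  cat("Interval vector:\n")
  for (k in seq_along(x$lower)) {
    cat(sprintf("  [%g, %g]\n", x$lower[k], x$upper[k]))
  }
  invisible(x)
}

#' Train an interval probabilistic neural network
#'
#' Builds one [density_model()] per class: the pattern sample is stored
#' verbatim (one kernel unit per training point), per-dimension smoothing
#' parameters are selected by the plug-in method, and per-point modification
#' coefficients with intensity `c` adapt the kernels to local sample
#' density.  Training is deterministic given the input.
#'
#' The Bayes prior enters through `prior`: with `"frequency"` (the default)
#' class j is weighted by its pattern count \eqn{m_j}, appropriate when
#' class sample sizes reflect the frequency of occurrence; with
#' `"uniform"` every class receives equal weight (the per-class densities
#' are compared directly), appropriate when pattern-set sizes are an
#' artefact of data collection rather than of prevalence.  For equinumerous
#' classes the two rules coincide.
#'
#' @param patterns a named list of numeric matrices (one per class, rows =
#'   pattern points, shared column count), or a `data.frame` together with
#'   `labels`.  Class order is the order of first appearance and is kept in
#'   the model.
#' @param labels optional vector of class labels, one per row of `patterns`,
#'   when `patterns` is a single matrix or data frame.
#' @param c modification intensity (>= 0), default 0.5.
#' @param prior `"frequency"` or `"uniform"`.
#' @param fallback logical; allow the normal-reference bandwidth when the
#'   plug-in selector fails (see [plugin_bandwidth()]).
#' @return an object of class `"ipnn"` with fields `labels`, `models`
#'   (list of density models), `sizes`, `prior`, `c`, `n`.
#' @examples
#' set.seed(1)
#' pats <- list(a = matrix(rnorm(40), ncol = 2),
#'              b = matrix(rnorm(40, 2), ncol = 2))
#' fit <- ipnn_fit(pats)
#' classify_point(fit, c(0, 0))$label
#' @export
ipnn_fit <- function(patterns, labels = NULL, c = 0.5,
                     prior = c("frequency", "uniform"), fallback = FALSE) {
  prior <- match.arg(prior)
  patterns <- split_patterns(patterns, labels)
  if (length(patterns) < 2L) {
    abort_invalid_argument("at least two classes are required")
  }
  dims <- vapply(patterns, ncol, integer(1))
  if (length(unique(dims)) != 1L) {
    abort_invalid_argument("all classes must share the same number of features")
  }
  sizes <- vapply(patterns, nrow, integer(1))
  if (any(sizes < 2L)) {
    abort_insufficient_data(sprintf(
      "every class needs at least 2 pattern points (violated by: %s)",
      paste(names(patterns)[sizes < 2L], collapse = ", ")
    ))
  }
  models <- lapply(names(patterns), function(lab) {
    tryCatch(
      density_model(patterns[[lab]], c = c, fallback = fallback),
      ipnn_error = function(e) {
        ipnn_abort(sprintf("class '%s': %s", lab, conditionMessage(e)),
                   class = setdiff(class(e), c("error", "condition")),
                   trace = e$trace)
      }
    )
  })
  names(models) <- names(patterns)
  structure(
    list(labels = names(patterns), models = models, sizes = unname(sizes),
         prior = prior, c = c, n = dims[[1]]),
    class = "ipnn"
  )
}

# Accept either a named list of matrices or (matrix/data.frame, labels).
split_patterns <- function(patterns, labels) {
  if (is.data.frame(patterns) || (is.matrix(patterns) && !is.null(labels))) {
    if (is.null(labels)) {
      abort_invalid_argument("`labels` must be supplied with a single data table")
    }
    X <- as.matrix(patterns)
    if (nrow(X) != length(labels)) {
      abort_invalid_argument("`labels` must have one entry per row")
    }
    labs <- as.character(labels)
    out <- lapply(unique(labs), function(l) X[labs == l, , drop = FALSE])
    names(out) <- unique(labs)
    return(out)
  }
  if (!is.list(patterns)) {
    abort_invalid_argument("`patterns` must be a named list of matrices or a data table with labels")
  }
  if (is.null(names(patterns)) || any(names(patterns) == "")) {
    names(patterns) <- paste0("class", seq_along(patterns))
  }
  if (anyDuplicated(names(patterns))) {
    abort_invalid_argument("class labels must be unique")
  }
  lapply(patterns, function(p) as.matrix(p))
}

#' @export
print.ipnn <- function(x, ...) {
  cat(sprintf("Interval probabilistic neural network (%d classes, %d features)\n",
              length(x$labels), x$n))
  cat(sprintf("  prior: %s; modification intensity c = %g\n", x$prior, x$c))
  for (j in seq_along(x$labels)) {
    cat(sprintf("  class '%s': m = %d, h = %s\n", x$labels[j], x$sizes[j],
                paste(format(x$models[[j]]$h, digits = 4), collapse = ", ")))
  }
  invisible(x)
}

class_weights <- function(model) {
  if (model$prior == "frequency") model$sizes else rep(1, length(model$sizes))
}

# N x J criterion matrix for a batch of interval queries.
# criterion_j = w_j * interval_mass_j (interval_mass already carries 1/m_j,
# so frequency weights recover the unnormalized sum of kernel masses).
ipnn_criteria <- function(model, lower, upper) {
  w <- class_weights(model)
  crit <- vapply(seq_along(model$models), function(j) {
    w[j] * interval_mass_batch(model$models[[j]], lower, upper)
  }, numeric(nrow(lower)))
  if (!is.matrix(crit)) crit <- matrix(crit, nrow = 1L)
  colnames(crit) <- model$labels
  crit
}

# Argmax with deterministic lowest-index tie-breaking; ties detected at
# relative tolerance TIE_REL_TOL.
decide <- function(crit, labels) {
  best <- max.col(crit, ties.method = "first")
  top <- crit[cbind(seq_len(nrow(crit)), best)]
  tie <- rowSums(crit >= top - TIE_REL_TOL * pmax(abs(top), 1)) >= 2L
  list(index = best, label = labels[best], tie = tie)
}

#' Classify a crisp (precisely known) point
#'
#' The classical probabilistic-neural-network decision: the per-class
#' criterion is the prior weight times the class density estimate at `x`,
#' and the predicted label attains the maximum.  Ties (equal criteria within
#' relative tolerance 1e-12) are broken towards the class listed first and
#' flagged.
#'
#' @param model an [ipnn_fit()] model.
#' @param x numeric vector of length n.
#' @return an object of class `"ipnn_decision"`: a list with `label`,
#'   `criteria` (named numeric vector) and `tie_flag`.
#' @export
classify_point <- function(model, x) {
  stopifnot(inherits(model, "ipnn"))
  X <- query_matrix(x, model$n)
  if (nrow(X) != 1L) abort_invalid_argument("`x` must be a single point; use predict() for batches")
  classify_interval(model, interval_vector(drop(X), drop(X)))
}

#' Classify an interval vector
#'
#' The Bayes decision for an imprecise query: the per-class criterion is the
#' prior weight times the probability mass the class estimator assigns to
#' the query box (computed analytically, see [interval_mass()]).  A fully
#' degenerate box yields exactly the crisp decision of [classify_point()].
#'
#' @param model an [ipnn_fit()] model.
#' @param q an [interval_vector()], or a numeric vector (taken as a crisp
#'   point).
#' @return an `"ipnn_decision"` (see [classify_point()]).
#' @export
classify_interval <- function(model, q) {
  stopifnot(inherits(model, "ipnn"))
  q <- as_interval_vector(q, model$n)
  crit <- ipnn_criteria(model, rbind(q$lower), rbind(q$upper))
  d <- decide(crit, model$labels)
  if (d$tie[1]) {
    message(sprintf("tie between classes {%s}; choosing '%s'",
                    paste(model$labels[crit[1, ] >= max(crit[1, ]) *
                                         (1 - TIE_REL_TOL)], collapse = ", "),
                    d$label[1]))
  }
  structure(
    list(label = d$label[1], criteria = drop(crit)[seq_along(model$labels)],
         tie_flag = d$tie[1]),
    class = "ipnn_decision"
  )
}

#' @export
print.ipnn_decision <- function(x, ...) {
  cat(sprintf("Predicted class: %s%s\n", x$label,
              if (x$tie_flag) " (tie)" else ""))
  cat("Criteria:\n")
  print(x$criteria)
  invisible(x)
}

#' Predict classes for a batch of queries
#'
#' @param object an [ipnn_fit()] model.
#' @param newdata either a numeric matrix of crisp points (N x n), or a list
#'   with matrices `lower` and `upper` (N x n each) describing N interval
#'   queries, or a list of [interval_vector()]s.
#' @param ... unused.
#' @return a `data.frame` with columns `label`, `tie`, and one criterion
#'   column per class (named `crit_<label>`).
#' @export
predict.ipnn <- function(object, newdata, ...) {
  bounds <- query_bounds(object, newdata)
  crit <- ipnn_criteria(object, bounds$lower, bounds$upper)
  d <- decide(crit, object$labels)
  out <- data.frame(label = d$label, tie = d$tie, stringsAsFactors = FALSE)
  for (j in seq_along(object$labels)) {
    out[[paste0("crit_", object$labels[j])]] <- crit[, j]
  }
  out
}

query_bounds <- function(model, newdata) {
  n <- model$n
  if (is.list(newdata) && !is.null(newdata$lower) && !is.null(newdata$upper)) {
    lower <- as.matrix(newdata$lower)
    upper <- as.matrix(newdata$upper)
    if (ncol(lower) != n || ncol(upper) != n || !all(dim(lower) == dim(upper))) {
      abort_invalid_argument("`lower` and `upper` must both be N x n matrices")
    }
    if (any(lower > upper)) {
      abort_invalid_interval(sprintf(
        "lower bound exceeds upper bound in row(s) %s",
        paste(utils::head(which(rowSums(lower > upper) > 0), 5), collapse = ", ")
      ))
    }
    return(list(lower = lower, upper = upper))
  }
  if (is.list(newdata) && all(vapply(newdata, inherits, logical(1), "interval_vector"))) {
    lower <- do.call(rbind, lapply(newdata, `[[`, "lower"))
    upper <- do.call(rbind, lapply(newdata, `[[`, "upper"))
    if (ncol(lower) != n) {
      abort_invalid_argument(sprintf("queries have %d features, model expects %d",
                                     ncol(lower), n))
    }
    return(list(lower = lower, upper = upper))
  }
  X <- query_matrix(newdata, n)
  list(lower = X, upper = X)
}

#' Assemble an IPNN from prebuilt density models
#'
#' Low-level constructor for composing a classifier from
#' [density_model()] objects directly, e.g. with hand-set bandwidths or
#' single-point classes.  [ipnn_fit()] is the normal entry point.
#'
#' @param models named list of [density_model()] objects sharing a common
#'   feature dimension; names are the class labels.
#' @param prior `"frequency"` or `"uniform"`.
#' @param c modification intensity recorded in the model (informational).
#' @return an object of class `"ipnn"`.
#' @export
ipnn_model <- function(models, prior = c("frequency", "uniform"), c = NA_real_) {
  prior <- match.arg(prior)
  if (!is.list(models) || length(models) < 2L ||
      !all(vapply(models, inherits, logical(1), "density_model"))) {
    abort_invalid_argument("`models` must be a named list of >= 2 density models")
  }
  if (is.null(names(models)) || anyDuplicated(names(models))) {
    abort_invalid_argument("`models` must have unique names")
  }
  dims <- vapply(models, `[[`, integer(1), "n")
  if (length(unique(dims)) != 1L) {
    abort_invalid_argument("all density models must share the feature dimension")
  }
  structure(
    list(labels = names(models), models = models,
         sizes = vapply(models, `[[`, integer(1), "m"),
         prior = prior, c = c, n = dims[[1]]),
    class = "ipnn"
  )
}
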