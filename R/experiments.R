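# Synthetic-data generators and seeded Monte-Carlo protocols measuring
# average misclassification of the interval classifier and of a simple
# counting baseline on Gaussian and Gaussian-mixture class designs.

#' Multivariate normal sample via Box-Muller
#'
#' Draws `count` rows from N(`mean`, I) using the Box-Muller transform on
#' uniform deviates from R's seeded generator: each pair of uniforms
#' \eqn{(u_1, u_2)} yields \eqn{\sqrt{-2\ln u_1}(\cos 2\pi u_2,
#' \sin 2\pi u_2)}.
#'
#' @param count number of rows (>= 1).
#' @param mean numeric mean vector; its length sets the dimension.
#' @return a `count` x `length(mean)` numeric matrix.
#' @export
mvn_sample <- function(count, mean) {
  check_finite_numeric(mean, "mean")
  if (length(count) != 1L || count < 1) {
    abort_invalid_argument("`count` must be a positive integer")
  }
  n <- length(mean)
  k <- count * n
  npairs <- ceiling(k / 2)
  u1 <- pmax(stats::runif(npairs), .Machine$double.xmin)
  u2 <- stats::runif(npairs)
  r <- sqrt(-2 * log(u1))
  z <- c(r * cos(2 * pi * u2), r * sin(2 * pi * u2))[seq_len(k)]
  matrix(z, nrow = count, ncol = n) + matrix(mean, count, n, byrow = TRUE)
}

#' Class specification: a Gaussian mixture with identity covariances
#'
#' @param means a matrix with one component mean per row (or a single mean
#'   vector for a unimodal class).
#' @param weights mixture weights, one per component, summing to 1.
#' @return a list of class `"class_spec"`.
#' @export
class_spec <- function(means, weights = NULL) {
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  means <- as.matrix(means)
  check_finite_numeric(means, "means")
  if (is.null(weights)) weights <- rep(1 / nrow(means), nrow(means))
  check_finite_numeric(weights, "weights")
  if (length(weights) != nrow(means) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort_invalid_argument("`weights` must be nonnegative, one per component, and sum to 1")
  }
  structure(list(means = means, weights = weights), class = "class_spec")
}

#' Sample from a Gaussian-mixture class specification
#'
#' Each draw picks a component with the specification's weights (via a
#' uniform deviate) and then samples from N(component mean, I) with
#' [mvn_sample()].
#'
#' @param spec a [class_spec()].
#' @param count number of draws.
#' @return a `count` x n matrix.
#' @export
mixture_sample <- function(spec, count) {
  if (!inherits(spec, "class_spec")) spec <- do.call(class_spec, spec)
  ncomp <- nrow(spec$means)
  if (ncomp == 1L) return(mvn_sample(count, spec$means[1, ]))
  u <- stats::runif(count)
  comp <- findInterval(u, cumsum(spec$weights)[-ncomp]) + 1L
  out <- matrix(NA_real_, count, ncol(spec$means))
  for (j in seq_len(ncomp)) {
    idx <- which(comp == j)
    if (length(idx)) out[idx, ] <- mvn_sample(length(idx), spec$means[j, ])
  }
  out
}

#' Wrap points into intervals of fixed length and random location
#'
#' Each coordinate of each point is embedded in an interval of the given
#' length whose position is uniform subject to containing the point: with
#' \eqn{u \sim U(0,1)} independently per coordinate, the bounds are
#' \eqn{[x - u\,\ell,\; x + (1-u)\,\ell]}.  Length 0 gives the degenerate
#' (crisp) box.
#'
#' @param points an N x n matrix of crisp points (or a single vector).
#' @param length interval length, a scalar >= 0.
#' @param u optional matrix/vector of uniforms to inject (for tests);
#'   drawn from the seeded generator when `NULL`.
#' @return for a vector input, an [interval_vector()]; for a matrix, a list
#'   with N x n matrices `lower` and `upper`.
#' @export
make_interval <- function(points, length, u = NULL) {
  if (!is.numeric(length) || base::length(length) != 1L || !is.finite(length) ||
      length < 0) {
    abort_invalid_argument("`length` must be a single number >= 0")
  }
  vec <- is.null(dim(points))
  X <- if (vec) matrix(points, nrow = 1L) else as.matrix(points)
  check_finite_numeric(X, "points")
  if (is.null(u)) {
    u <- matrix(stats::runif(base::length(X)), nrow(X), ncol(X))
  } else {
    u <- matrix(u, nrow(X), ncol(X))
    if (any(u < 0 | u > 1)) abort_invalid_argument("`u` must lie in [0, 1]")
  }
  lower <- X - u * length
  upper <- lower + length
  if (vec) interval_vector(drop(lower), drop(upper)) else list(lower = lower, upper = upper)
}

#' Monte-Carlo experiment configuration
#'
#' Describes a synthetic classification study: the class designs, the grid
#' of pattern-set sizes and interval lengths, the test-set size, the number
#' of repetitions, and the classifier options.
#'
#' @param class_specs named list of [class_spec()]s (>= 2 classes).
#' @param m_grid list of integer vectors, each giving the per-class pattern
#'   sizes of one grid row (a single integer is recycled to all classes).
#' @param interval_lengths numeric vector of interval lengths (>= 0); every
#'   coordinate of a query uses the same length.
#' @param test_per_class test items drawn per class per repetition.
#' @param repetitions Monte-Carlo repetitions per grid cell.
#' @param seed integer seed; the whole experiment is a deterministic
#'   function of it.
#' @param c modification intensity passed to [ipnn_fit()].
#' @param prior prior mode passed to [ipnn_fit()].
#' @return a list of class `"experiment_config"`.
#' @export
experiment_config <- function(class_specs, m_grid, interval_lengths,
                              test_per_class = 1000, repetitions = 100,
                              seed = 1, c = 0.5,
                              prior = c("frequency", "uniform")) {
  prior <- match.arg(prior)
  if (!is.list(class_specs) || length(class_specs) < 2L) {
    abort_invalid_argument("`class_specs` must list at least two classes")
  }
  if (is.null(names(class_specs)) || anyDuplicated(names(class_specs))) {
    abort_invalid_argument("`class_specs` must have unique names")
  }
  class_specs <- lapply(class_specs, function(s) {
    if (inherits(s, "class_spec")) s else do.call(class_spec, s)
  })
  J <- length(class_specs)
  m_grid <- lapply(m_grid, function(m) {
    m <- as.integer(m)
    if (length(m) == 1L) m <- rep(m, J)
    if (length(m) != J || any(m < 2L)) {
      abort_invalid_argument("each `m_grid` entry needs one size >= 2 per class")
    }
    m
  })
  check_finite_numeric(interval_lengths, "interval_lengths")
  if (any(interval_lengths < 0)) {
    abort_invalid_argument("`interval_lengths` must be >= 0")
  }
  structure(
    list(class_specs = class_specs, m_grid = m_grid,
         interval_lengths = interval_lengths,
         test_per_class = as.integer(test_per_class),
         repetitions = as.integer(repetitions),
         seed = as.integer(seed), c = c, prior = prior),
    class = "experiment_config"
  )
}

m_label <- function(m) paste(m, collapse = "/")

#' Run a Monte-Carlo misclassification experiment
#'
#' For every pattern-size row of the grid and every repetition: draw fresh
#' pattern sets, train the classifier, draw `test_per_class` crisp test
#' points per class, wrap them into interval queries of each configured
#' length (length 0 exercises the crisp PNN path), classify, and record
#' error rates.  The total error is the fraction of misclassified items over
#' all test items; per-class errors are each computed over that class's own
#' test items.  The run is a deterministic function of `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress lines.
#' @return an object of class `"ipnn_experiment"`: a list with
#'   `reports[[m]][[length]]` (each holding `mean_error`,
#'   `per_class_errors`, `repetition_errors`, `standard_error`),
#'   a long-format `tidy` data frame (one row per repetition and cell) and a
#'   `summary` data frame of mean errors (one row per grid cell).
#' @export
run_error_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  labels <- names(config$class_specs)
  J <- length(labels)
  lengths <- config$interval_lengths
  ntest <- config$test_per_class
  truth <- rep(labels, each = ntest)

  reports <- list()
  tidy <- list()
  for (m in config$m_grid) {
    key <- m_label(m)
    rep_err <- matrix(NA_real_, config$repetitions, length(lengths))
    rep_cls <- array(NA_real_, c(config$repetitions, length(lengths), J))
    for (r in seq_len(config$repetitions)) {
      patterns <- lapply(seq_len(J), function(j) {
        mixture_sample(config$class_specs[[j]], m[j])
      })
      names(patterns) <- labels
      fit <- ipnn_fit(patterns, c = config$c, prior = config$prior)
      test <- do.call(rbind, lapply(seq_len(J), function(j) {
        mixture_sample(config$class_specs[[j]], ntest)
      }))
      for (li in seq_along(lengths)) {
        q <- make_interval(test, lengths[li])
        pred <- predict(fit, q)$label
        wrong <- pred != truth
        rep_err[r, li] <- mean(wrong)
        for (j in seq_len(J)) {
          rep_cls[r, li, j] <- mean(wrong[truth == labels[j]])
        }
      }
      if (verbose && r %% 10 == 0) {
        message(sprintf("m = %s: repetition %d/%d", key, r, config$repetitions))
      }
    }
    reports[[key]] <- list()
    for (li in seq_along(lengths)) {
      per_class <- colMeans(rep_cls[, li, , drop = FALSE])[1, , drop = TRUE]
      names(per_class) <- labels
      reports[[key]][[as.character(lengths[li])]] <- list(
        mean_error = mean(rep_err[, li]),
        per_class_errors = per_class,
        repetition_errors = rep_err[, li],
        standard_error = stats::sd(rep_err[, li]) / sqrt(config$repetitions)
      )
    }
    cell <- expand.grid(repetition = seq_len(config$repetitions),
                        length = lengths, KEEP.OUT.ATTRS = FALSE)
    cell$m <- key
    cell$error <- as.vector(rep_err)
    for (j in seq_len(J)) {
      cell[[paste0("error_", labels[j])]] <- as.vector(rep_cls[, , j])
    }
    tidy[[key]] <- cell
  }
  tidy <- do.call(rbind, tidy)
  rownames(tidy) <- NULL
  summary <- do.call(rbind, lapply(names(reports), function(key) {
    do.call(rbind, lapply(names(reports[[key]]), function(lk) {
      rp <- reports[[key]][[lk]]
      data.frame(m = key, length = as.numeric(lk),
                 mean_error = rp$mean_error,
                 standard_error = rp$standard_error,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(config = config, reports = reports,
                 tidy = tidy, summary = summary),
            class = "ipnn_experiment")
}

#' @export
print.ipnn_experiment <- function(x, ...) {
  cat(sprintf("Monte-Carlo classification experiment (%d repetitions, %d test items/class)\n",
              x$config$repetitions, x$config$test_per_class))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Counting-rule classification of an interval query
#'
#' The baseline rule: count how many pattern points of each class fall
#' inside the closed query box; predict the class with the strictly largest
#' count, report `"equal"` when the positive maximum is shared, and
#' `"none"` when no pattern point lies inside.
#'
#' @param patterns named list of pattern matrices (one per class).
#' @param q an [interval_vector()].
#' @return a single character string: a class label, `"equal"`, or `"none"`.
#' @export
counting_classify <- function(patterns, q) {
  patterns <- lapply(patterns, as.matrix)
  n <- ncol(patterns[[1]])
  q <- as_interval_vector(q, n)
  counts <- counting_counts(patterns, rbind(q$lower), rbind(q$upper))
  counting_outcome(counts, names(patterns))[1]
}

# counts: N x J matrix of pattern points inside each box (closed bounds)
counting_counts <- function(patterns, lower, upper) {
  N <- nrow(lower)
  vapply(patterns, function(P) {
    inside <- matrix(TRUE, N, nrow(P))
    for (k in seq_len(ncol(P))) {
      pk <- rep(P[, k], each = N)
      inside <- inside &
        (pk >= lower[, k]) & (pk <= upper[, k])
    }
    as.numeric(rowSums(inside))
  }, numeric(N))
}

counting_outcome <- function(counts, labels) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1L)
  top <- apply(counts, 1L, max)
  ntop <- rowSums(counts == top)
  out <- labels[max.col(counts, ties.method = "first")]
  out[top == 0] <- "none"
  out[top > 0 & ntop >= 2] <- "equal"
  out
}

#' Run the counting-baseline experiment
#'
#' Same sampling protocol as [run_error_experiment()] (two classes), but
#' queries are classified by [counting_classify()].  Per grid cell the
#' report contains the rate of outright wrong decisions (`error`), the rate
#' of tied positive counts (`equal_rate`), the rate of empty boxes
#' (`none_rate`), and the total `full_error = error + 0.5 (equal_rate +
#' none_rate)` - the expected error when ties and empty boxes are resolved
#' by a fair coin between the two equinumerous classes.
#'
#' @param config an [experiment_config()] with exactly two classes.
#' @param verbose print progress lines.
#' @return an object of class `"counting_experiment"` with
#'   `reports[[m]][[length]]` and a `summary` data frame.
#' @export
run_counting_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$class_specs) != 2L) {
    abort_invalid_argument("the counting experiment requires exactly two classes")
  }
  set.seed(config$seed)
  labels <- names(config$class_specs)
  lengths <- config$interval_lengths
  ntest <- config$test_per_class
  truth <- rep(labels, each = ntest)

  reports <- list()
  for (m in config$m_grid) {
    key <- m_label(m)
    acc <- array(NA_real_, c(config$repetitions, length(lengths), 4L))
    for (r in seq_len(config$repetitions)) {
      patterns <- lapply(seq_along(labels), function(j) {
        mixture_sample(config$class_specs[[j]], m[j])
      })
      names(patterns) <- labels
      test <- do.call(rbind, lapply(seq_along(labels), function(j) {
        mixture_sample(config$class_specs[[j]], ntest)
      }))
      for (li in seq_along(lengths)) {
        q <- make_interval(test, lengths[li])
        counts <- counting_counts(patterns, q$lower, q$upper)
        outcome <- counting_outcome(counts, labels)
        err <- mean(outcome != truth & outcome != "equal" & outcome != "none")
        eq <- mean(outcome == "equal")
        none <- mean(outcome == "none")
        acc[r, li, ] <- c(err, eq, none, err + 0.5 * (eq + none))
      }
      if (verbose && r %% 10 == 0) {
        message(sprintf("m = %s: repetition %d/%d", key, r, config$repetitions))
      }
    }
    reports[[key]] <- list()
    for (li in seq_along(lengths)) {
      v <- colMeans(acc[, li, , drop = FALSE])[1, , drop = TRUE]
      reports[[key]][[as.character(lengths[li])]] <- list(
        error = v[1], equal_rate = v[2], none_rate = v[3], full_error = v[4],
        repetition_full_errors = acc[, li, 4],
        standard_error = stats::sd(acc[, li, 4]) / sqrt(config$repetitions)
      )
    }
  }
  summary <- do.call(rbind, lapply(names(reports), function(key) {
    do.call(rbind, lapply(names(reports[[key]]), function(lk) {
      rp <- reports[[key]][[lk]]
      data.frame(m = key, length = as.numeric(lk), error = rp$error,
                 equal_rate = rp$equal_rate, none_rate = rp$none_rate,
                 full_error = rp$full_error, stringsAsFactors = FALSE)
    }))
  }))
  structure(list(config = config, reports = reports, summary = summary),
            class = "counting_experiment")
}

#' @export
print.counting_experiment <- function(x, ...) {
  cat(sprintf("Counting-baseline experiment (%d repetitions, %d test items/class)\n",
              x$config$repetitions, x$config$test_per_class))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
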