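# Typed error conditions used across the package.  Every error signalled by
# ipnn carries class "ipnn_error" plus a more specific subclass so callers
# (and the CLI) can react programmatically.

ipnn_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "ipnn_error")))
}

abort_invalid_argument <- function(message, ...) {
  ipnn_abort(message, "ipnn_invalid_argument", ...)
}

abort_insufficient_data <- function(message, ...) {
  ipnn_abort(message, "ipnn_insufficient_data", ...)
}

abort_degenerate_sample <- function(message, ...) {
  ipnn_abort(message, "ipnn_degenerate_sample", ...)
}

abort_plugin_failure <- function(message, trace, ...) {
  ipnn_abort(message, "ipnn_plugin_failure", trace = trace, ...)
}

abort_invalid_interval <- function(message, ...) {
  ipnn_abort(message, "ipnn_invalid_interval", ...)
}

abort_schema <- function(message, ...) {
  ipnn_abort(message, "ipnn_schema_error", ...)
}

check_finite_numeric <- function(x, name, allow_infinite = FALSE) {
  if (!is.numeric(x)) {
    abort_invalid_argument(sprintf("`%s` must be numeric", name))
  }
  if (anyNA(x)) {
    abort_invalid_argument(sprintf("`%s` contains NA/NaN values", name))
  }
  if (!allow_infinite && any(!is.finite(x))) {
    abort_invalid_argument(sprintf("`%s` contains non-finite values", name))
  }
  invisible(x)
}
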