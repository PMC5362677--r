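# Closed-form kernel layer: the Cauchy estimator kernel, its antiderivative,
# the MISE constants R(K) and P(K), and the standard-normal pilot-kernel
# derivatives consumed by the plug-in bandwidth selector.

#' Cauchy estimator kernel
#'
#' The one-dimensional kernel used throughout the package,
#' \deqn{\mathcal{K}(t) = \frac{2}{\pi (t^2 + 1)^2},}
#' a symmetric unit-integral density with heavy (quartic) tails.  Its appeal
#' here is that its antiderivative is elementary (see
#' [cauchy_kernel_cdf()]), so integrals of kernel density estimates over
#' boxes are available in closed form.
#'
#' @param t numeric vector of evaluation points; must be finite.
#' @return numeric vector of density values, strictly positive.
#' @seealso [cauchy_kernel_cdf()], [cauchy_kernel_constants()]
#' @examples
#' cauchy_kernel(0)        # 2/pi
#' cauchy_kernel(c(-1, 1)) # symmetric
#' @export
cauchy_kernel <- function(t) {
  check_finite_numeric(t, "t")
  2 / (pi * (t^2 + 1)^2)
}

#' Antiderivative (CDF) of the Cauchy estimator kernel
#'
#' The fully normalized primitive
#' \deqn{\mathcal{J}(t) = \frac{1}{\pi}\left(\arctan t +
#'   \frac{t}{1 + t^2}\right) + \frac{1}{2},}
#' i.e. the cumulative distribution function of [cauchy_kernel()]:
#' nondecreasing with \eqn{\mathcal{J}(-\infty) = 0} and
#' \eqn{\mathcal{J}(+\infty) = 1}.  Infinite arguments are mapped to exactly
#' 0 and 1.
#'
#' @param t numeric vector; infinite values allowed, NA/NaN rejected.
#' @return numeric vector of cumulative probabilities in \[0, 1\].
#' @examples
#' cauchy_kernel_cdf(0)    # 0.5
#' cauchy_kernel_cdf(Inf)  # 1
#' @export
cauchy_kernel_cdf <- function(t) {
  check_finite_numeric(t, "t", allow_infinite = TRUE)
  out <- numeric(length(t))
  pos <- t == Inf
  neg <- t == -Inf
  fin <- !(pos | neg)
  out[pos] <- 1
  out[neg] <- 0
  tf <- t[fin]
  out[fin] <- (atan(tf) + tf / (1 + tf^2)) / pi + 0.5
  out
}

#' Kernel constants for the plug-in bandwidth selector
#'
#' Returns the constants entering the asymptotically optimal smoothing
#' formula: the roughness \eqn{R(\mathcal{K}) = \int \mathcal{K}(t)^2 dt =
#' 5/(4\pi)} and second moment \eqn{P(\mathcal{K}) = \int t^2 \mathcal{K}(t)
#' dt = 1} of the Cauchy estimator kernel, together with the standard-normal
#' pilot kernel's derivative values at zero,
#' \eqn{K_1^{(4)}(0) = 3/\sqrt{2\pi}}, \eqn{K_1^{(6)}(0) = -15/\sqrt{2\pi}},
#' \eqn{K_1^{(8)}(0) = 105/\sqrt{2\pi}}, and its unit second moment.  The
#' alternating sign pattern of the pilot derivatives (positive, negative,
#' positive) is what keeps every radicand in the plug-in stages positive for
#' well-behaved samples.
#'
#' @return a list of class `"kernel_constants"` with fields `roughness_R`,
#'   `second_moment_P`, `pilot_deriv4_at0`, `pilot_deriv6_at0`,
#'   `pilot_deriv8_at0`, `pilot_second_moment`.
#' @export
cauchy_kernel_constants <- function() {
  structure(
    list(
      roughness_R        = 5 / (4 * pi),
      second_moment_P    = 1,
      pilot_deriv4_at0   = 3 / sqrt(2 * pi),
      pilot_deriv6_at0   = -15 / sqrt(2 * pi),
      pilot_deriv8_at0   = 105 / sqrt(2 * pi),
      pilot_second_moment = 1
    ),
    class = "kernel_constants"
  )
}

# Probabilists' Hermite polynomial He_r evaluated via the three-term
# recurrence He_{k+1}(t) = t He_k(t) - k He_{k-1}(t).
hermite_he <- function(r, t) {
  h0 <- rep(1, length(t))
  if (r == 0) return(h0)
  h1 <- t
  if (r == 1) return(h1)
  for (k in 1:(r - 1)) {
    h2 <- t * h1 - k * h0
    h0 <- h1
    h1 <- h2
  }
  h1
}

#' Derivatives of the standard-normal pilot kernel
#'
#' Evaluates the r-th derivative of the standard normal density via the
#' Hermite identity \eqn{\phi^{(r)}(t) = (-1)^r He_r(t) \phi(t)}
#' (probabilists' convention).  Only the even orders used by the plug-in
#' stages are supported.
#'
#' @param r derivative order, one of 4, 6, 8.
#' @param t numeric vector of finite evaluation points.
#' @return numeric vector, finite for all `t`.
#' @export
gaussian_pilot_derivative <- function(r, t) {
  if (length(r) != 1L || !(r %in% c(4, 6, 8))) {
    abort_invalid_argument("`r` must be one of 4, 6, 8")
  }
  check_finite_numeric(t, "t")
  # (-1)^r = 1 for the even orders supported here
  hermite_he(r, t) * stats::dnorm(t)
}
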