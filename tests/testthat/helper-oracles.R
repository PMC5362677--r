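# Shared oracles and fixture builders.  Oracles are independent of the code
# paths they check: numerical quadrature (stats::integrate, pracma),
# symbolic differentiation (stats::D), and brute-force double loops.

# r-fold symbolic derivative of the standard normal density, evaluated at t.
# Independent of the Hermite-recurrence implementation under test.
symbolic_dnorm_deriv <- function(r, t) {
  e <- quote(exp(-x^2 / 2) / sqrt(2 * pi))
  for (i in seq_len(r)) e <- stats::D(e, "x")
  vapply(t, function(tt) eval(e, list(x = tt)), numeric(1))
}

# Quadrature of a 1-d function over the real line (maps through atan).
quad_line <- function(f, ...) {
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12, ...)$value
}

# Mass of a density model over [a, b] (1-d) by adaptive quadrature.
quad_mass_1d <- function(model, a, b) {
  stats::integrate(function(x) kde_evaluate(model, matrix(x, ncol = 1)),
                   a, b, rel.tol = 1e-10, abs.tol = 1e-13)$value
}

# Mass of a 2-d density model over a box by pracma's adaptive 2-d quadrature.
quad_mass_2d <- function(model, lo, hi) {
  pracma::integral2(function(x, y) {
    X <- cbind(as.vector(x), as.vector(y))
    matrix(kde_evaluate(model, X), nrow = nrow(as.matrix(x)))
  }, lo[1], hi[1], lo[2], hi[2], reltol = 1e-10)$Q
}

# Random small density model for property tests.
random_model <- function(m = 6, n = 1, c = 0.5) {
  pts <- matrix(stats::rnorm(m * n, sd = runif(1, 0.5, 2)), m, n)
  h <- stats::runif(n, 0.3, 1.5)
  density_model(pts, h = h, c = c)
}

# Two-class Gaussian fixture patterns (1-d unless dim given).
gauss_patterns <- function(m, dim = 1, delta = 2) {
  list(c1 = matrix(stats::rnorm(m * dim), m, dim),
       c2 = matrix(stats::rnorm(m * dim), m, dim) +
         matrix(c(delta, rep(0, dim - 1)), m, dim, byrow = TRUE))
}
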