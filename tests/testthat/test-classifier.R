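test_that("fit builds one density model per class and is deterministic", {
  set.seed(41)
  pats <- gauss_patterns(8, dim = 2)
  fit <- ipnn_fit(pats)
  expect_s3_class(fit, "ipnn")
  expect_equal(fit$labels, c("c1", "c2"))
  expect_equal(fit$sizes, c(8L, 8L))
  expect_true(all(vapply(fit$models, function(m) all(m$h > 0), logical(1))))
  expect_true(all(vapply(fit$models, function(m) length(m$s) == 8, logical(1))))

  refit <- ipnn_fit(pats)
  expect_identical(fit, refit)

  expect_error(ipnn_fit(pats["c1"]), class = "ipnn_invalid_argument")
  expect_error(ipnn_fit(list(a = matrix(1:4, 2), b = matrix(1:6, 2))),
               class = "ipnn_invalid_argument")
  expect_error(ipnn_fit(list(a = matrix(1, 1, 1), b = matrix(1:2, 2, 1))),
               class = "ipnn_insufficient_data")
})

test_that("fit accepts a data frame with labels and keeps first-appearance order", {
  set.seed(42)
  df <- data.frame(x = rnorm(9), y = rnorm(9))
  labs <- c("b", "a", "b", "a", "b", "a", "b", "a", "b")
  fit <- ipnn_fit(df, labels = labs)
  expect_equal(fit$labels, c("b", "a"))
  expect_equal(fit$sizes, c(5L, 4L))
})

test_that("joint positive scaling scales h and leaves s unchanged", {
  set.seed(43)
  pats <- gauss_patterns(10)
  a <- 3.7
  fit <- ipnn_fit(pats)
  fit_scaled <- ipnn_fit(lapply(pats, function(p) a * p))
  for (j in 1:2) {
    expect_equal(fit_scaled$models[[j]]$h, a * fit$models[[j]]$h,
                 tolerance = 1e-9)
    expect_equal(fit_scaled$models[[j]]$s, fit$models[[j]]$s,
                 tolerance = 1e-9)
  }
})

test_that("crisp decisions follow the weighted density argmax with deterministic ties", {
  # symmetric single-kernel classes with forced equal bandwidths
  sym <- ipnn_model(list(
    left = density_model(matrix(-2), h = 1, s = 1, c = 0),
    right = density_model(matrix(2), h = 1, s = 1, c = 0)
  ))
  d <- suppressMessages(classify_point(sym, 0))
  expect_true(d$tie_flag)
  expect_equal(d$label, "left")

  asym <- ipnn_model(list(
    a = density_model(matrix(0), h = 1, s = 1, c = 0),
    b = density_model(matrix(2), h = 1, s = 1, c = 0)
  ))
  d2 <- classify_point(asym, 0.2)
  expect_equal(d2$label, "a")
  expect_false(d2$tie_flag)
  expect_equal(unname(d2$criteria),
               c(cauchy_kernel(0.2), cauchy_kernel(1.8)), tolerance = 1e-12)
})

test_that("frequency weighting never favours the small class more than uniform", {
  set.seed(44)
  big <- matrix(rnorm(100), ncol = 1)
  small <- matrix(rnorm(10, 2), ncol = 1)
  freq <- ipnn_fit(list(c1 = big, c2 = small), prior = "frequency")
  unif <- ipnn_fit(list(c1 = big, c2 = small), prior = "uniform")
  grid <- matrix(seq(-3, 5, length.out = 200), ncol = 1)
  n_c1_freq <- sum(predict(freq, grid)$label == "c1")
  n_c1_unif <- sum(predict(unif, grid)$label == "c1")
  expect_gte(n_c1_freq, n_c1_unif)
})

test_that("interval decisions: total-mass box, quadrature agreement", {
  set.seed(45)
  fit <- ipnn_fit(list(c1 = matrix(rnorm(30)), c2 = matrix(rnorm(10, 2))),
                  prior = "frequency")
  # infinite box: criterion_j = m_j, so the larger class wins
  d <- classify_interval(fit, interval_vector(-Inf, Inf))
  expect_equal(unname(d$criteria), c(30, 10), tolerance = 1e-9)
  expect_equal(d$label, "c1")

  # random boxes agree with the quadrature-based argmax
  for (i in 1:10) {
    a <- runif(1, -2, 2)
    b <- a + runif(1, 0.1, 3)
    d <- classify_interval(fit, interval_vector(a, b))
    quad_crit <- c(30, 10) * c(quad_mass_1d(fit$models$c1, a, b),
                               quad_mass_1d(fit$models$c2, a, b))
    expect_equal(unname(d$criteria), unname(quad_crit), tolerance = 1e-8)
    expect_equal(d$label, c("c1", "c2")[which.max(quad_crit)])
  }
})

test_that("decisions are invariant to row permutation and joint affine rescaling", {
  set.seed(46)
  pats <- gauss_patterns(12)
  fit <- ipnn_fit(pats)
  perm <- ipnn_fit(lapply(pats, function(p) p[sample(nrow(p)), , drop = FALSE]))
  a <- 2.5; b <- -7
  resc <- ipnn_fit(lapply(pats, function(p) a * p + b))
  queries <- matrix(runif(50, -3, 5), ncol = 1)
  lo <- queries - 0.3
  hi <- queries + 0.6
  base <- predict(fit, list(lower = lo, upper = hi))
  expect_equal(predict(perm, list(lower = lo, upper = hi))$label, base$label)
  expect_equal(
    predict(resc, list(lower = a * lo + b, upper = a * hi + b))$label,
    base$label
  )
})

test_that("criteria are finite, nonnegative, and sum to total pattern count on R^n", {
  set.seed(47)
  fit <- ipnn_fit(gauss_patterns(7, dim = 2), prior = "frequency")
  d <- classify_interval(fit, interval_vector(c(-Inf, -Inf), c(Inf, Inf)))
  expect_true(all(is.finite(d$criteria)) && all(d$criteria >= 0))
  expect_equal(sum(d$criteria), sum(fit$sizes), tolerance = 1e-9)
})

test_that("degenerate interval queries reproduce crisp decisions exactly", {
  set.seed(48)
  fit <- ipnn_fit(gauss_patterns(15, dim = 2))
  X <- cbind(runif(1000, -3, 5), runif(1000, -3, 3))
  crisp <- predict(fit, X)
  degen <- predict(fit, list(lower = X, upper = X))
  expect_identical(crisp$label, degen$label)
})
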