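test_that("sample_std validates and matches the two-point formula", {
  expect_equal(sample_std(c(0, 2)), sqrt(2), tolerance = 1e-12)
  expect_error(sample_std(c(5, 5, 5)), class = "ipnn_degenerate_sample")
  expect_error(sample_std(3), class = "ipnn_insufficient_data")
  expect_error(sample_std(c(1, NA)), class = "ipnn_invalid_argument")
  set.seed(42)
  expect_equal(sample_std(rnorm(1e6)), 1, tolerance = 0.005)
})

test_that("normal-scale psi10 matches its closed form and power law", {
  expect_equal(psi_normal_scale(1), -945 / (64 * sqrt(pi)), tolerance = 1e-12)
  expect_equal(psi_normal_scale(2), psi_normal_scale(1) / 2^11, tolerance = 1e-12)
  expect_lt(psi_normal_scale(1), 0)
  expect_error(psi_normal_scale(0), class = "ipnn_invalid_argument")
  expect_error(psi_normal_scale(-1), class = "ipnn_invalid_argument")
})

test_that("psi_hat equals the brute-force double sum including the diagonal", {
  # all-zero differences: every pair contributes K1^(r)(0)
  expect_equal(psi_hat(4, 1, c(0, 0)), 3 / sqrt(2 * pi), tolerance = 1e-12)
  expect_error(psi_hat(4, 1, 0), class = "ipnn_insufficient_data")
  expect_error(psi_hat(4, -1, c(0, 1)), class = "ipnn_invalid_argument")

  set.seed(7)
  x <- rnorm(50)
  for (r in c(4, 6, 8)) {
    for (g in c(0.5, 1.3)) {
      naive <- 0
      for (i in seq_along(x)) {
        for (j in seq_along(x)) {
          naive <- naive + symbolic_dnorm_deriv(r, (x[i] - x[j]) / g)
        }
      }
      naive <- naive / (length(x)^2 * g^(r + 1))
      expect_equal(psi_hat(r, g, x), naive, tolerance = 1e-10)
    }
  }
  # blocked evaluation agrees with itself across block boundaries
  set.seed(8)
  y <- rnorm(1030)
  expect_equal(psi_hat(4, 0.4, y), psi_hat(4, 0.4, rev(y)), tolerance = 1e-12)
})

test_that("plug-in chain is translation invariant and scale equivariant", {
  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(30, mean = runif(1, -5, 5), sd = runif(1, 0.2, 3))
    a <- runif(1, 0.1, 10)
    b <- runif(1, -20, 20)
    h0 <- plugin_bandwidth(x)$h
    expect_equal(plugin_bandwidth(a * x)$h, a * h0, tolerance = 1e-9)
    expect_equal(plugin_bandwidth(x + b)$h, h0, tolerance = 1e-9)
  }
})

test_that("plug-in trace has the normal-reference sign pattern and positive stages", {
  set.seed(3)
  tr <- plugin_bandwidth(rnorm(200))$trace
  expect_lt(tr$psi10_ns, 0)
  expect_gt(tr$psi8, 0)
  expect_lt(tr$psi6, 0)
  expect_gt(tr$psi4, 0)
  expect_true(all(c(tr$g1, tr$g2, tr$g3, tr$h) > 0))
  expect_false(tr$fallback_used)
})

test_that("psi4 stays positive for Gaussian samples in >= 99% of seeded trials", {
  set.seed(99)
  ok <- replicate(1000, {
    res <- tryCatch(plugin_bandwidth(rnorm(20)), ipnn_error = function(e) NULL)
    !is.null(res) && res$trace$psi4 > 0
  })
  expect_gte(mean(ok), 0.99)
})

test_that("bandwidth shrinks with sample size at roughly the m^(-1/5) rate", {
  set.seed(12)
  x <- rnorm(10000)
  h100 <- plugin_bandwidth(x[1:100])$h
  h1k <- plugin_bandwidth(x[1:1000])$h
  h10k <- plugin_bandwidth(x)$h
  expect_lt(h1k, h100)
  expect_lt(h10k, h1k)
  # the decade ratio fluctuates per draw; its Monte-Carlo average must sit
  # near 10^(-1/5)
  ratios <- c(h1k / h100, h10k / h1k,
              replicate(8, {
                y <- rnorm(1000)
                plugin_bandwidth(y)$h / plugin_bandwidth(y[1:100])$h
              }))
  expect_equal(mean(ratios), 10^(-1 / 5), tolerance = 0.15)
})

test_that("bandwidth_vector applies the selector per column", {
  set.seed(5)
  x <- rnorm(80)
  X <- cbind(x, x, 3 * x)
  bw <- bandwidth_vector(X)
  expect_equal(bw$h[1], bw$h[2], tolerance = 1e-12)
  expect_equal(bw$h[3], 3 * bw$h[1], tolerance = 1e-9)
  expect_equal(bandwidth_vector(matrix(x, ncol = 1))$h,
               plugin_bandwidth(x)$h, tolerance = 1e-14)
  # per-column failures carry the column index
  bad <- cbind(x, rep(1, 80))
  err <- tryCatch(bandwidth_vector(bad), ipnn_error = function(e) e)
  expect_s3_class(err, "ipnn_degenerate_sample")
  expect_match(conditionMessage(err), "column 2")
})

test_that("plug-in chain survives pathological samples; fallback formula is correct", {
  # heavy tails, lattices and separated clusters all keep the functional
  # sign chain intact (the guard exists for safety, not for common data)
  set.seed(17)
  pathological <- c(
    lapply(1:20, function(i) rt(8, df = 1)),
    list(as.numeric(0:9), c(rep(0, 5), rep(50, 5)) + rnorm(10, 0, 1e-6),
         c(rnorm(3, 0, 0.01), rnorm(3, 2, 0.01), rnorm(3, 4, 0.01)))
  )
  for (x in pathological) {
    res <- plugin_bandwidth(x, fallback = TRUE)
    expect_gt(res$h, 0)
    expect_false(res$trace$fallback_used)
  }
  # the normal-reference substitute equals its closed form:
  # h_NS = (R(K) / (m * R(f''_phi)))^(1/5) with R(f''_phi) = 3/(8 sqrt(pi) sigma^5)
  expect_equal(ipnn:::normal_scale_bandwidth(1, 100),
               (5 / (4 * pi) / (100 * 3 / (8 * sqrt(pi))))^(1 / 5),
               tolerance = 1e-12)
  expect_equal(ipnn:::normal_scale_bandwidth(2, 100),
               2 * ipnn:::normal_scale_bandwidth(1, 100), tolerance = 1e-12)
})
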