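test_that("Box-Muller generator has the right moments and is seed-deterministic", {
  set.seed(51)
  X <- mvn_sample(1e5, c(0, 0))
  expect_equal(dim(X), c(1e5, 2))
  expect_lt(max(abs(colMeans(X))), 0.02)
  expect_lt(max(abs(stats::cov(X) - diag(2))), 0.02)

  set.seed(52); A <- mvn_sample(100, c(1, -1))
  set.seed(52); B <- mvn_sample(100, c(1, -1))
  expect_identical(A, B)
  expect_equal(dim(mvn_sample(1, c(0, 0, 0))), c(1, 3))
  expect_error(mvn_sample(0, 0), class = "ipnn_invalid_argument")
})

test_that("mixture sampling respects component weights and means", {
  expect_error(class_spec(rbind(c(0, 0), c(2, 0)), c(0.7, 0.7)),
               class = "ipnn_invalid_argument")

  # single component behaves like the plain generator
  set.seed(53); A <- mixture_sample(class_spec(c(1, 2)), 50)
  set.seed(53); B <- mvn_sample(50, c(1, 2))
  expect_identical(A, B)

  # trimodal spec: component proportions within 0.01 of 1/3
  spec1 <- class_spec(rbind(c(0, 0), c(2, 0), c(4, 0)), rep(1 / 3, 3))
  set.seed(54)
  X <- mixture_sample(spec1, 3e5)
  near <- apply(abs(outer(X[, 1], c(0, 2, 4), "-")), 1, which.min)
  # first coordinate means 0/2/4 are 2 apart, so assignment by nearest mean
  # recovers components up to small overlap; proportions must be ~1/3
  expect_lt(max(abs(table(near) / 3e5 - 1 / 3)), 0.015)

  # bimodal spec: overall mean at the weight-average of the components
  spec2 <- class_spec(rbind(c(1, sqrt(3)), c(3, sqrt(3))), c(0.5, 0.5))
  set.seed(55)
  Y <- mixture_sample(spec2, 3e5)
  expect_lt(max(abs(colMeans(Y) - c(2, sqrt(3)))), 0.02)
})

test_that("interval wrapping always contains the point with exact width", {
  expect_error(make_interval(0, -1), class = "ipnn_invalid_argument")
  iv0 <- make_interval(c(1, 2), 0)
  expect_equal(iv0$lower, c(1, 2))
  expect_equal(iv0$upper, c(1, 2))

  iv <- make_interval(0, 1, u = 0.3)
  expect_equal(iv$lower, -0.3, tolerance = 1e-15)
  expect_equal(iv$upper, 0.7, tolerance = 1e-15)

  set.seed(56)
  X <- matrix(rnorm(2e5), ncol = 2)
  q <- make_interval(X, 0.4)
  expect_true(all(abs((q$upper - q$lower) - 0.4) < 1e-12))
  expect_true(all(q$lower <= X & X <= q$upper))
})

test_that("counting rule matches enumeration on closed boxes", {
  pats <- list(c1 = matrix(c(0, 0.5)), c2 = matrix(2))
  expect_equal(counting_classify(pats, interval_vector(-0.1, 0.6)), "c1")
  expect_equal(counting_classify(pats, interval_vector(0.9, 1.1)), "none")
  # shared positive maximum across single-point classes
  single <- list(c1 = matrix(0), c2 = matrix(2))
  expect_equal(counting_classify(single, interval_vector(-1, 3)), "equal")
  expect_equal(counting_classify(single, interval_vector(0.9, 1.1)), "none")
  # boundary membership is closed
  expect_equal(counting_classify(pats, interval_vector(0.5, 0.7)), "c1")
  expect_equal(counting_classify(pats, interval_vector(2, 2)), "c2")
})

test_that("counting experiment satisfies its accounting identity and limits", {
  cfg <- experiment_config(
    list(c1 = class_spec(0), c2 = class_spec(2)),
    m_grid = list(20L), interval_lengths = c(0.5, 1e6),
    test_per_class = 200, repetitions = 5, seed = 57
  )
  res <- run_counting_experiment(cfg)
  for (rp in res$reports[["20/20"]]) {
    expect_equal(rp$full_error,
                 rp$error + 0.5 * (rp$equal_rate + rp$none_rate),
                 tolerance = 1e-12)
  }
  # an absurdly long interval contains every pattern point: all ties
  huge <- res$reports[["20/20"]][["1e+06"]]
  expect_equal(huge$equal_rate, 1, tolerance = 1e-12)
  expect_equal(huge$full_error, 0.5, tolerance = 1e-12)
})

test_that("error experiment is seed-reproducible and ~0.5 for identical classes", {
  cfg <- experiment_config(
    list(c1 = class_spec(0), c2 = class_spec(0)),
    m_grid = list(15L), interval_lengths = c(0, 0.5),
    test_per_class = 300, repetitions = 8, seed = 58
  )
  res1 <- run_error_experiment(cfg)
  res2 <- run_error_experiment(cfg)
  expect_identical(res1$summary, res2$summary)
  expect_identical(res1$tidy, res2$tidy)

  for (rp in res1$reports[["15/15"]]) {
    expect_equal(rp$mean_error, mean(rp$repetition_errors), tolerance = 1e-12)
    expect_lt(abs(rp$mean_error - 0.5), 3 * rp$standard_error + 0.02)
  }
})

test_that("experiment presets encode the documented designs", {
  t1 <- experiment_preset("table1")
  expect_equal(length(t1$class_specs), 2L)
  expect_equal(t1$class_specs$class2$means, matrix(2))
  expect_equal(t1$interval_lengths, c(0, 0.1, 0.25, 0.5, 1, 2, 5))
  expect_equal(t1$m_grid[[1]], c(10L, 10L))

  t5 <- experiment_preset("table5", m = c(10, 100))
  expect_equal(t5$m_grid, list(c(20L, 10L), c(200L, 100L)))
  expect_equal(t5$prior, "uniform")

  t7 <- experiment_preset("table7")
  expect_equal(nrow(t7$class_specs$class1$means), 3L)
  expect_equal(t7$class_specs$class2$means[, 2], rep(sqrt(3), 2))

  expect_error(experiment_preset("table99"), class = "ipnn_invalid_argument")
})

test_that("misclassification decreases with pattern size in a quick seeded study", {
  cfg <- experiment_preset("table1", m = c(10, 200), lengths = 0,
                           repetitions = 10, test_per_class = 500, seed = 59)
  res <- run_error_experiment(cfg)
  e10 <- res$reports[["10/10"]][["0"]]
  e200 <- res$reports[["200/200"]][["0"]]
  se <- sqrt(e10$standard_error^2 + e200$standard_error^2)
  expect_gt(e10$mean_error, e200$mean_error - 3 * se)
})
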