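test_that("covariates are Uniform(-1, 1) with the right moments", {
  X <- generate_covariates(20000, seed = 1)
  expect_true(all(X > -1 & X < 1))
  expect_true(all(abs(colMeans(X)) < 0.02))
  expect_true(all(abs(apply(X, 2, var) - 1 / 3) < 0.01))
})

test_that("outcome probability rows are valid under both interpretations and links", {
  X <- generate_covariates(500, seed = 2)
  for (link in c("logit", "probit")) {
    for (interp in c("softmax", "literal")) {
      pr <- outcome_probabilities(X, link, interp)
      expect_true(all(pr >= 0))
      expect_equal(rowSums(pr), rep(1, 500), tolerance = 1e-8)
    }
  }
  # softmax rows are strictly interior
  pr <- outcome_probabilities(X, "logit", "softmax")
  expect_true(all(pr > 0 & pr < 1))
})

test_that("generated outcomes follow the per-row probabilities", {
  set.seed(3)
  X <- matrix(rep(c(0.5, -0.2, 0.1, 0, 0.3), each = 20000), 20000, 5)
  pr <- outcome_probabilities(X, "logit", "softmax")[1, ]
  y <- generate_outcome(X, "logit", "softmax", seed = 4)
  expect_true(max(abs(tabulate(y, 3) / 20000 - pr)) < 0.01)
})

test_that("M1 is non-extreme and M2 U-shaped, both with about 50% missingness", {
  X <- generate_covariates(200000, seed = 5)
  p1 <- missingness_probabilities(X, "M1", "logit")
  p2 <- missingness_probabilities(X, "M2", "logit")
  expect_equal(mean(1 - p1), 0.5, tolerance = 0.01)
  expect_equal(mean(1 - p2), 0.5, tolerance = 0.01)
  # M2 puts at least 10% of its mass near each boundary
  expect_gt(mean(p2 < 0.1), 0.10)
  expect_gt(mean(p2 > 0.9), 0.10)
  # M1 is less extreme than M2
  expect_lt(mean(p1 < 0.1 | p1 > 0.9), mean(p2 < 0.1 | p2 > 0.9))

  delta <- generate_missingness(X[1:50000, ], "M1", "logit", seed = 6)
  expect_equal(mean(delta == 0), 0.5, tolerance = 0.02)
})

test_that("calibration machinery selects a candidate matching its reference", {
  # against the softmax generator's own marginals the softmax candidate matches
  ref <- as.numeric(true_marginals("logit", "softmax", n_mc = 8e6, seed = 7))[1:2]
  cal <- calibrate_generator("logit", n_mc = 1e6, seed = 8, reference = ref)
  expect_true(cal$matched)
  expect_equal(cal$selected, "softmax")
  expect_equal(nrow(cal$report), 2L)
  # strict mode errors when nothing can match
  expect_error(
    calibrate_generator("logit", n_mc = 1e6, seed = 9,
                        reference = c(0.9, 0.05), strict = TRUE),
    "no generator candidate")
})

test_that("Monte Carlo error formulas are exact", {
  df <- data.frame(sd = c(0.034, 0.02), cr = c(0.95, 0.5))
  attr(df, "R") <- 500L
  m <- monte_carlo_errors(df)
  expect_equal(m$mce_est[1], 0.034 / sqrt(500))
  expect_equal(m$mce_sd[1], 0.034 / sqrt(2 * 499))
  expect_equal(m$mce_cr[1], sqrt(0.95 * 0.05 / 500))
  # quadrupling R halves MCE(EST)
  attr(df, "R") <- 2000L
  expect_equal(monte_carlo_errors(df)$mce_est, m$mce_est / 2)
})

test_that("scenario configuration encodes the five misspecification patterns", {
  expect_equal(scenario_config(1)$outcome_covs, 1:3)
  expect_equal(scenario_config(1)$prop_covs, 1:5)
  expect_equal(scenario_config(2)$prop_covs, 1:3)
  expect_equal(scenario_config(3)$outcome_link, "probit")
  expect_equal(scenario_config(3)$miss_link, "logit")
  expect_equal(scenario_config(4)$miss_link, "probit")
  expect_equal(scenario_config(5)$outcome_link, "probit")
  expect_equal(scenario_config(5)$miss_link, "probit")
  expect_error(scenario_config(0, weights = list(c(0.5, 0.4, 0.2))), "sum to 1")
})

test_that("run_scenario aggregates paired replicates deterministically", {
  cfg <- scenario_config(0, n = 150, R = 4,
                         methods = c("fo", "cc", "pmi", "nnmi_mlr"),
                         weights = list(c(0.4, 0.4, 0.2)), K = 3, ce_B = 0,
                         seed = 31)
  res <- run_scenario(cfg, truth = c(0.345, 0.29, 0.365))
  expect_s3_class(res, "simulation_result")
  expect_equal(sort(unique(res$method)), c("cc", "fo", "nnmi_mlr", "pmi"))
  expect_equal(nrow(res), 4L * 3L)
  expect_equal(attr(res, "R"), 4L)
  expect_equal(attr(res, "dropped"), 0L)
  # estimates across categories average to one within each method
  for (m in unique(res$label)) {
    expect_equal(sum(res$est[res$label == m]), 1, tolerance = 1e-10)
  }
  res2 <- run_scenario(cfg, truth = c(0.345, 0.29, 0.365))
  expect_identical(res$est, res2$est)
})

test_that("fully observed analysis attains its nominal coverage against the MC truth", {
  cfg <- scenario_config(0, n = 400, R = 300, methods = "fo", seed = 41)
  truth <- as.numeric(true_marginals("logit", "softmax", n_mc = 2e6, seed = 42))
  res <- run_scenario(cfg, truth = truth)
  # EST recovers the truth within 3 Monte Carlo errors
  for (k in 1:3) {
    row <- res[res$category == k, ]
    expect_lt(abs(row$est - truth[k]), 3 * row$mce_est + 1e-4)
  }
  expect_true(all(abs(res$cr - 0.95) < 3 * sqrt(0.95 * 0.05 / 300) + 0.015))
})
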