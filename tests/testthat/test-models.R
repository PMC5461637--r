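test_that("working_model_spec validates family, link, and covariate subset", {
  s <- working_model_spec("propensity", 1:3, link = "probit")
  expect_equal(s$link, "probit")
  expect_error(working_model_spec("mlr", 1:5, link = "probit"), "logit link only")
  expect_error(working_model_spec("mlr", integer(0)), "non-empty")
  expect_error(working_model_spec("mlr", c(1, 1, 2)), "unique")
})

test_that("zero-coefficient models give the closed-form scores", {
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(outcome_scores(zero_outcome_model("mlr"), X),
               matrix(1 / 3, 5, 2), ignore_attr = TRUE)
  expect_equal(outcome_scores(zero_outcome_model("clr"), X),
               matrix(1 / 2, 5, 2), ignore_attr = TRUE)
  expect_equal(propensity_scores(zero_propensity_model(), X), rep(0.5, 5))
  expect_equal(propensity_scores(zero_propensity_model(link = "probit"), X),
               rep(0.5, 5))
})

test_that("MLR scores plus the baseline term sum to one and lie in (0,1)", {
  set.seed(21)
  for (rep in 1:5) {
    co <- matrix(rnorm(6, sd = 2), 2, 3)
    spec <- working_model_spec("mlr", 1:3, intercept = FALSE)
    m <- nnmicat:::new_fitted_wm(spec, co, TRUE, 0, 3L, 10L)
    X <- matrix(rnorm(30), 10, 3)
    sc <- outcome_scores(m, X)
    expect_true(all(sc > 0 & sc < 1))
    baseline <- 1 / (1 + rowSums(exp(X %*% t(co))))
    expect_equal(rowSums(sc) + baseline, rep(1, 10), tolerance = 1e-10)
  }
})

test_that("propensity score is monotone in a positive-coefficient covariate", {
  spec <- working_model_spec("propensity", 1, intercept = FALSE)
  m <- nnmicat:::new_fitted_wm(spec, matrix(2, 1, 1), TRUE, 0, 2L, 10L)
  x <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  expect_true(all(diff(propensity_scores(m, x)) > 0))
})

test_that("outcome fits recover the working-model structure on simulated data", {
  sim <- toy_data(600, seed = 31)
  fit <- fit_outcome_model(sim$data, mlr5)
  expect_s3_class(fit, "fitted_wm")
  expect_equal(dim(fit$coefficients), c(2L, 6L))
  expect_true(fit$converged)
  sc <- outcome_scores(fit, sim$data$X)
  expect_true(all(sc > 0 & sc < 1))

  cfit <- fit_outcome_model(sim$data, clr5)
  expect_equal(dim(cfit$coefficients), c(2L, 6L))
  expect_true(all(outcome_scores(cfit, sim$data$X) > 0))
})

test_that("CLR and MLR coincide for a binary outcome", {
  set.seed(41)
  X <- generate_covariates(500, p = 2)
  y <- 1L + as.integer(runif(500) < plogis(X %*% c(1, -1)))
  d <- incomplete_data(X, y, M = 2)
  s_mlr <- outcome_scores(fit_outcome_model(d, working_model_spec("mlr", 1:2)), X)
  s_clr <- outcome_scores(fit_outcome_model(d, working_model_spec("clr", 1:2)), X)
  expect_equal(s_mlr, s_clr, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("degenerate fitting samples raise redraw signals", {
  X <- matrix(rnorm(20), 10, 2)
  # all complete-case outcomes identical
  expect_degenerate(fit_outcome_model(
    incomplete_data(X, c(rep(2L, 5), rep(NA, 5)), M = 3),
    working_model_spec("mlr", 1:2)))
  # a required level absent for the multinomial fit
  expect_degenerate(fit_outcome_model(
    incomplete_data(X, c(1L, 1L, 2L, 2L, 1L, rep(NA, 5)), M = 3),
    working_model_spec("mlr", 1:2)))
  # CLR tolerates a missing middle level but not a one-sided cut
  set.seed(77)
  X40 <- matrix(rnorm(80), 40, 2)
  d13 <- incomplete_data(X40, sample(c(1L, 3L), 40, replace = TRUE), M = 3)
  expect_s3_class(fit_outcome_model(d13, working_model_spec("clr", 1:2)),
                  "fitted_wm")
  expect_degenerate(fit_outcome_model(d13, working_model_spec("mlr", 1:2)))
  # constant missingness indicator
  expect_degenerate(fit_propensity_model(
    incomplete_data(X, rep(1L, 10), M = 2),
    working_model_spec("propensity", 1:2)))
})

test_that("probit and logit propensity working models both converge on logit-generated data", {
  sim <- toy_data(400, seed = 51)
  f_logit <- fit_propensity_model(sim$data, prop5)
  f_probit <- fit_propensity_model(
    sim$data, working_model_spec("propensity", 1:5, link = "probit"))
  expect_true(f_logit$converged && f_probit$converged)
  expect_false(isTRUE(all.equal(f_logit$coefficients, f_probit$coefficients,
                                check.attributes = FALSE)))
  # fitted observation probabilities average near the 50% design value
  # (single dataset of n = 400, so allow ~3 binomial SEs)
  expect_lt(abs(mean(propensity_scores(f_logit, sim$data$X)) - 0.5), 0.08)
})

test_that("standardization centres and scales columns and handles degeneracy", {
  s <- standardize_scores(cbind(c(1, 2, 3)))
  expect_equal(s$scores[, 1], c(-1, 0, 1))

  expect_warning(z <- standardize_scores(cbind(a = c(2, 2, 2), b = c(1, 2, 3))),
                 "zero variance")
  expect_equal(z$scores[, "a"], c(0, 0, 0))

  set.seed(61)
  raw <- matrix(rnorm(40), 10, 4)
  once <- standardize_scores(raw)$scores
  twice <- standardize_scores(once)$scores
  expect_equal(once, twice, tolerance = 1e-12)

  # reusing the returned transform reproduces the same mapping on new rows
  tr <- standardize_scores(raw)
  new_rows <- matrix(rnorm(8), 2, 4)
  manual <- sweep(sweep(new_rows, 2, tr$center), 2, tr$scale, `/`)
  expect_equal(standardize_scores(new_rows, tr$center, tr$scale)$scores,
               manual, ignore_attr = TRUE)
})
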