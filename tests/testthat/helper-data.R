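# Small fixtures built from the package's own generators.

toy_data <- function(n = 120, seed = 11, miss_model = "M1",
                     outcome_link = "logit") {
  simulate_dataset(n, outcome_link = outcome_link, miss_model = miss_model,
                   seed = seed)
}

mlr5 <- working_model_spec("mlr", 1:5)
clr5 <- working_model_spec("clr", 1:5)
prop5 <- working_model_spec("propensity", 1:5)

# Zero-coefficient fitted models for closed-form score checks.
zero_outcome_model <- function(family = "mlr", M = 3, p = 2) {
  spec <- working_model_spec(family, seq_len(p), intercept = FALSE)
  nnmicat:::new_fitted_wm(spec, matrix(0, M - 1, p), TRUE, 0, M, 10L)
}

zero_propensity_model <- function(p = 2, link = "logit") {
  spec <- working_model_spec("propensity", seq_len(p), link = link,
                             intercept = FALSE)
  nnmicat:::new_fitted_wm(spec, matrix(0, 1, p), TRUE, 0, 2L, 10L)
}

expect_degenerate <- function(expr) {
  expect_error(expr, class = "nnmicat_degenerate_fit")
}
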