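test_that("score_distance is a weighted Euclidean metric", {
  w <- c(0.4, 0.4, 0.2)
  expect_equal(score_distance(c(1, 2, 3), c(1, 2, 3), w), 0)
  expect_equal(score_distance(c(1, 0, 0), c(0, 0, 0), w), sqrt(0.4))
  # symmetry
  a <- c(0.3, -1, 2); b <- c(1, 0.5, -0.2)
  expect_equal(score_distance(a, b, w), score_distance(b, a, w))
  # zero-weight coordinates are ignored entirely
  expect_equal(score_distance(c(0, 5, -7), c(0, 2, 11), c(1, 0, 0)), 0)
  expect_error(score_distance(a, b, c(0.5, 0.4)), "sum to 1")
  expect_error(score_distance(a, b, c(1.4, -0.4, 0)), "non-negative")
})

test_that("donor_set returns the nn smallest distances, matching brute force", {
  w <- c(0.5, 0.3, 0.2)
  # all donors returned when nn equals the donor count
  set.seed(71)
  donors <- matrix(rnorm(15), 5, 3)
  expect_setequal(donor_set(c(0, 0, 0), donors, w, 5), 1:5)

  # known ordering
  d1 <- cbind(c(0.1, 0.2, 0.3, 0.9), 0, 0)
  expect_setequal(donor_set(c(0, 0, 0), d1, c(1, 0, 0), 2), c(1L, 2L))

  # brute-force oracle on random configurations with n <= 20
  for (case in 1:20) {
    set.seed(100 + case)
    nd <- sample(5:20, 1)
    nn <- sample(1:nd, 1)
    q <- rnorm(3)
    donors <- matrix(rnorm(3 * nd), nd, 3)
    dist_all <- apply(donors, 1, function(r) score_distance(q, r, w))
    got <- donor_set(q, donors, w, nn)
    expect_equal(sort(dist_all[got]), sort(dist_all)[seq_len(nn)],
                 tolerance = 1e-12)
  }
})

test_that("equidistant donors are selected reproducibly and uniformly", {
  donors <- matrix(1, 5, 3)  # all at the same distance from the query
  w <- c(1, 1, 1) / 3
  set.seed(81); first <- donor_set(c(0, 0, 0), donors, w, 3)
  set.seed(81); again <- donor_set(c(0, 0, 0), donors, w, 3)
  expect_identical(first, again)

  set.seed(82)
  counts <- integer(5)
  reps <- 4000
  for (i in seq_len(reps)) {
    sel <- donor_set(c(0, 0, 0), donors, w, 3)
    counts[sel] <- counts[sel] + 1L
  }
  # each donor should appear in about 3/5 of draws
  expect_true(all(abs(counts / reps - 0.6) < 0.04))
})

test_that("Rubin's rules match hand-computed pooling", {
  mk <- function(est, se) structure(
    list(est = est, se = se, K = nrow(est), M = ncol(est), n = 100,
         method = "toy"),
    class = "imputation_result")
  r <- rubin_combine(mk(rbind(0.3, 0.5), rbind(0.1, 0.1)))
  expect_equal(r$est, 0.4)
  expect_equal(r$se, sqrt(0.01 + 1.5 * 0.02))  # = 0.2 exactly
  expect_equal(r$se, 0.2)

  # identical estimates: between-imputation term vanishes
  r2 <- rubin_combine(mk(rbind(0.3, 0.3, 0.3), rbind(0.1, 0.2, 0.15)))
  expect_equal(r2$se, sqrt(mean(c(0.1, 0.2, 0.15)^2)))

  # pooled SE never falls below the within-imputation component
  set.seed(91)
  est <- matrix(runif(12, 0.2, 0.8), 4, 3)
  se <- matrix(runif(12, 0.01, 0.1), 4, 3)
  r3 <- rubin_combine(mk(est, se))
  expect_true(all(r3$se >= sqrt(colMeans(se^2)) - 1e-12))

  expect_error(rubin_combine(mk(rbind(0.3), rbind(0.1))), "K must be >= 2")
})

test_that("nnmi with no missing values returns the sample proportions exactly", {
  set.seed(101)
  X <- generate_covariates(60)
  y <- generate_outcome(X)
  d <- incomplete_data(X, y, M = 3)
  r <- nnmi_impute(d, mlr5, prop5, c(0.4, 0.4, 0.2), K = 3, seed = 5)
  expect_true(all(r$completed == y))
  comb <- rubin_combine(r)
  expect_equal(comb$est, tabulate(y, 3) / 60)
  expect_equal(apply(r$est, 2, var), rep(0, 3))
})

test_that("imputation preserves observed values and yields coherent estimates", {
  sim <- toy_data(150, seed = 111)
  d <- sim$data
  r <- nnmi_impute(d, mlr5, prop5, c(0.4, 0.4, 0.2), K = 4, seed = 6)
  obs <- d$delta == 1L
  for (k in 1:4) {
    expect_identical(r$completed[obs, k], d$Y[obs])
    expect_false(anyNA(r$completed[, k]))
    expect_true(all(r$completed[, k] %in% 1:3))
  }
  expect_equal(rowSums(r$est), rep(1, 4))
  comb <- rubin_combine(r)
  expect_equal(sum(comb$est), 1)
  expect_true(all(comb$est >= 0 & comb$est <= 1))
})

test_that("pure predictive-score and pure propensity matching both run", {
  sim <- toy_data(120, seed = 121)
  r1 <- nnmi_impute(sim$data, mlr5, prop5, c(0.5, 0.5, 0), K = 2, seed = 7)
  r2 <- nnmi_impute(sim$data, mlr5, prop5, c(0, 0, 1), K = 2, seed = 7)
  expect_s3_class(r1, "imputation_result")
  expect_s3_class(r2, "imputation_result")
  # CLR outcome model works through the same interface
  r3 <- nnmi_impute(sim$data, clr5, prop5, c(0.4, 0.4, 0.2), K = 2, seed = 7)
  expect_false(anyNA(r3$completed))
})

test_that("with nn equal to the donor count imputation is a uniform donor draw", {
  set.seed(131)
  X <- generate_covariates(60)
  y <- generate_outcome(X)
  miss <- 1:20
  ymiss <- y; ymiss[miss] <- NA
  d <- incomplete_data(X, ymiss, M = 3)
  spec2 <- working_model_spec("mlr", 1:2)
  pspec2 <- working_model_spec("propensity", 1:2)
  # nn larger than any possible donor count errors
  expect_error(
    nnmi_impute(d, spec2, pspec2, c(0.4, 0.4, 0.2), nn = 61, K = 2, seed = 8),
    "donors|redraws")
  # nn close to the donor count: imputation approaches a uniform draw over
  # the bootstrap donors, so the imputed level frequency approaches the
  # complete-case distribution
  r <- nnmi_impute(d, spec2, pspec2, c(0, 0, 1), nn = 30, K = 300, seed = 9)
  cc_prop <- tabulate(y[-miss], 3) / 40
  imp_freq <- tabulate(r$completed[miss[1], ], 3) / 300
  expect_true(max(abs(imp_freq - cc_prop)) < 0.12)
})

test_that("identical seeds give identical imputations", {
  sim <- toy_data(130, seed = 141)
  r1 <- nnmi_impute(sim$data, mlr5, prop5, c(0.4, 0.4, 0.2), K = 3, seed = 17)
  r2 <- nnmi_impute(sim$data, mlr5, prop5, c(0.4, 0.4, 0.2), K = 3, seed = 17)
  expect_identical(r1$completed, r2$completed)
  r3 <- nnmi_impute(sim$data, mlr5, prop5, c(0.4, 0.4, 0.2), K = 3, seed = 18)
  expect_false(identical(r1$completed, r3$completed))
})
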