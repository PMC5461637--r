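bernoulli_cat_estimate <- function(y, M, n_eff, method, level = 0.95) {
  p <- tabulate(y, M) / n_eff
  se <- sqrt(p * (1 - p) / n_eff)
  z <- stats::qnorm(1 - (1 - level) / 2)
  cat_estimate(p, se, pmax(0, p - z * se), pmin(1, p + z * se),
               method = method, n_eff = n_eff)
}

#' Fully observed (gold standard) estimate
#'
#' Category proportions of a complete outcome vector, with Bernoulli
#' standard errors `sqrt(p (1 - p) / n)`. In simulations this is applied to
#' the outcome before any values are masked and serves as the benchmark.
#'
#' @param Y_full integer vector with entries in `1..M`, no missing values.
#' @param M number of categories (default `max(Y_full)`).
#' @return A `cat_estimate` data frame.
#' @examples
#' fo_estimate(c(1, 1, 2, 3))$est # 0.50 0.25 0.25
#' @export
fo_estimate <- function(Y_full, M = max(Y_full)) {
  if (anyNA(Y_full)) stop("fo_estimate requires a complete outcome", call. = FALSE)
  bernoulli_cat_estimate(as.integer(Y_full), as.integer(M),
                         length(Y_full), "fo")
}

#' Complete-case estimate
#'
#' Category proportions among subjects with observed outcome only, with
#' Bernoulli standard errors on the complete-case denominator. Biased under
#' missingness at random whenever the outcome and the missingness share
#' covariates.
#'
#' @param data an [incomplete_data] object with at least one complete case.
#' @return A `cat_estimate` data frame.
#' @export
cc_estimate <- function(data) {
  stopifnot(inherits(data, "incomplete_data"))
  cc <- complete_cases(data)
  if (!length(cc)) stop("no complete cases", call. = FALSE)
  bernoulli_cat_estimate(data$Y[cc], data$M, length(cc), "cc")
}

#' Calibration-estimator point estimate from fitted components
#'
#' The doubly robust calibration estimator for `Pr(Y = m)`:
#' `n^{-1} sum_i Phat_{i,m} + n^{-1} sum_i delta_i w_i (I_{i,m} - Phat_{i,m})`
#' with inverse-probability weights `w_i = 1 / pihat(X_i)`. The first term
#' averages the outcome-model predictions over all subjects; the second is
#' the weighted mean of complete-case prediction errors. Estimates sum to 1
#' across categories but individual entries can fall outside `[0, 1]`.
#'
#' @param P_hat n x M matrix of predicted category probabilities.
#' @param pi_hat length-n vector of predicted observation probabilities;
#'   clipped to `[1e-6, 1]` before inversion (clip count reported via
#'   attribute `n_clipped`).
#' @param delta length-n 0/1 missingness indicator.
#' @param Y length-n outcome (NA where `delta == 0`).
#' @return Numeric vector of M calibration estimates with attribute
#'   `n_clipped`.
#' @export
ce_point <- function(P_hat, pi_hat, delta, Y) {
  P_hat <- as.matrix(P_hat)
  n <- nrow(P_hat)
  M <- ncol(P_hat)
  clipped <- sum(pi_hat < 1e-6 & delta == 1L)
  w <- 1 / pmin(pmax(pi_hat, 1e-6), 1)
  I <- matrix(0, n, M)
  obs <- which(delta == 1L)
  I[cbind(obs, Y[obs])] <- 1
  est <- colMeans(P_hat) + colMeans(delta * w * (I - P_hat))
  attr(est, "n_clipped") <- clipped
  est
}

#' Calibration estimator
#'
#' Fits the outcome working model (MLR) on the complete cases and the
#' propensity working model on all subjects, then evaluates the calibration
#' estimator [ce_point()] for every category. Consistent if at least one of
#' the two working models is correctly specified, but unstable when some
#' estimated observation probabilities approach zero. Standard errors, when
#' requested, come from [ce_bootstrap_se()].
#'
#' @param data an [incomplete_data] object.
#' @param outcome_spec [working_model_spec] with family `"mlr"` (full
#'   category probabilities are required).
#' @param propensity_spec [working_model_spec] for the missingness model.
#' @param se_B bootstrap replicates for the standard error; `0` (default)
#'   returns point estimates with `NA` standard errors.
#' @param seed optional seed (used by the bootstrap when `se_B > 0`).
#' @param level confidence level for Wald intervals.
#' @return A `cat_estimate` data frame (attribute `n_clipped` records how
#'   many observed-case weights were clipped).
#' @export
ce_estimate <- function(data, outcome_spec, propensity_spec,
                        se_B = 0L, seed = NULL, level = 0.95) {
  stopifnot(inherits(data, "incomplete_data"))
  if (outcome_spec$family != "mlr") {
    stop("the calibration estimator requires an MLR outcome model", call. = FALSE)
  }
  om <- fit_outcome_model(data, outcome_spec)
  pm <- fit_propensity_model(data, propensity_spec)
  est_raw <- ce_point(mlr_category_probs(om, data$X),
                      propensity_scores(pm, data$X),
                      data$delta, data$Y)
  n_clipped <- attr(est_raw, "n_clipped")
  est <- as.numeric(est_raw)
  se <- rep(NA_real_, data$M)
  if (se_B >= 2L) {
    se <- ce_bootstrap_se(data, outcome_spec, propensity_spec,
                          B = se_B, seed = seed)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cat_estimate(est, se, est - z * se, est + z * se,
                      method = "ce", n_eff = data$n)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Bootstrap standard error of the calibration estimator
#'
#' Standard deviation of the calibration point estimates over `B`
#' with-replacement resamples of the full dataset, refitting both working
#' models on each resample. Resamples whose complete cases cannot support
#' the fits are redrawn (at most `max_redraws` attempts each).
#'
#' @inheritParams ce_estimate
#' @param B number of bootstrap resamples (>= 2); default 200.
#' @param max_redraws redraw limit per resample.
#' @return Numeric vector of M bootstrap standard errors.
#' @export
ce_bootstrap_se <- function(data, outcome_spec, propensity_spec,
                            B = 200L, seed = NULL, max_redraws = 100L) {
  stopifnot(inherits(data, "incomplete_data"))
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  set_seed_if_given(seed)
  n <- data$n
  ests <- matrix(NA_real_, B, data$M)
  for (b in seq_len(B)) {
    ests[b, ] <- with_redraws(function(attempt) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- incomplete_data(data$X[idx, , drop = FALSE], data$Y[idx], M = data$M)
      om <- fit_outcome_model(boot, outcome_spec)
      pm <- fit_propensity_model(boot, propensity_spec)
      as.numeric(ce_point(mlr_category_probs(om, boot$X),
                          propensity_scores(pm, boot$X),
                          boot$delta, boot$Y))
    }, max_redraws)
  }
  apply(ests, 2L, stats::sd)
}

#' Parametric multiple imputation
#'
#' Proper parametric MI with an MLR imputation model: each of the `K`
#' rounds bootstraps the dataset, refits the multinomial logistic regression
#' on the bootstrap complete cases, computes predicted category
#' probabilities for each original subject with missing outcome, and draws
#' the imputed level from that categorical distribution. Per-imputation
#' estimates are the completed-data category proportions with Bernoulli
#' standard errors; combine with [rubin_combine()].
#'
#' @param data an [incomplete_data] object.
#' @param outcome_spec [working_model_spec] with family `"mlr"`.
#' @param K number of imputations (>= 2); default 10.
#' @param seed optional integer seed.
#' @param max_redraws bootstrap redraw limit.
#' @return An `imputation_result` (see [nnmi_impute()]).
#' @export
pmi_impute <- function(data, outcome_spec, K = 10L, seed = NULL,
                       max_redraws = 100L) {
  stopifnot(inherits(data, "incomplete_data"))
  if (outcome_spec$family != "mlr") {
    stop("pmi_impute requires an MLR outcome model", call. = FALSE)
  }
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  set_seed_if_given(seed)
  n <- data$n
  miss <- which(data$delta == 0L)
  completed <- matrix(rep(data$Y, K), n, K)
  if (length(miss)) {
    for (k in seq_len(K)) {
      completed[miss, k] <- with_redraws(function(attempt) {
        idx <- sample.int(n, n, replace = TRUE)
        boot <- incomplete_data(data$X[idx, , drop = FALSE], data$Y[idx], M = data$M)
        om <- fit_outcome_model(boot, outcome_spec)
        pr <- mlr_category_probs(om, data$X[miss, , drop = FALSE])
        vapply(seq_along(miss), function(i) {
          sample.int(data$M, 1L, prob = pr[i, ])
        }, integer(1))
      }, max_redraws)
    }
  }
  est <- t(apply(completed, 2L, function(y) tabulate(y, data$M) / n))
  se <- sqrt(est * (1 - est) / n)
  structure(
    list(completed = completed, est = est, se = se, K = K, nn = NA_integer_,
         w = NULL, M = data$M, n = n, method = "pmi", seed = seed),
    class = "imputation_result"
  )
}
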