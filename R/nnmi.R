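#' Validate a predictive-score weight vector
#'
#' The distance between two subjects is a weighted Euclidean distance over
#' the `M` standardized predictive scores: weights `w[1..M-1]` belong to the
#' outcome-model scores and `w[M]` to the missingness-propensity score.
#' Weights must be non-negative and sum to one (tolerance `1e-10`). Setting
#' `w[M] = 0` gives pure predictive-score matching; `w = c(0, ..., 0, 1)`
#' gives pure propensity matching — both are legitimate sensitivity analyses.
#'
#' @param w numeric vector of length `M`.
#' @return The validated weight vector, invisibly unchanged.
#' @export
check_weights <- function(w) {
  w <- as.numeric(w)
  if (anyNA(w) || any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-10) stop("weights must sum to 1", call. = FALSE)
  w
}

#' Weighted score distance between two subjects
#'
#' `d(i, j) = sqrt(sum_m w_m (S_m(i) - S_m(j))^2)` over the `M` standardized
#' predictive scores.
#'
#' @param s_i,s_j numeric score vectors of length `M`.
#' @param w weight vector of length `M` (see [check_weights()]).
#' @return Non-negative scalar distance.
#' @examples
#' score_distance(c(1, 0, 0), c(0, 0, 0), c(0.4, 0.4, 0.2)) # sqrt(0.4)
#' @export
score_distance <- function(s_i, s_j, w) {
  w <- check_weights(w)
  if (length(s_i) != length(w) || length(s_j) != length(w)) {
    stop("score vectors and weights must have equal length", call. = FALSE)
  }
  sqrt(sum(w * (s_i - s_j)^2))
}

# All query-to-donor weighted distances at once: queries (nq x M),
# donors (nd x M) -> nq x nd matrix.
distance_matrix <- function(queries, donors, w) {
  qw <- sweep(queries, 2L, sqrt(w), `*`)
  dw <- sweep(donors, 2L, sqrt(w), `*`)
  qn <- rowSums(qw^2)
  dn <- rowSums(dw^2)
  d2 <- outer(qn, dn, `+`) - 2 * tcrossprod(qw, dw)
  sqrt(pmax(d2, 0))
}

#' Donor (imputing) set for one missing subject
#'
#' Returns the indices of the `nn` donors with the smallest weighted score
#' distances to the query. Ties at the cut-off are broken by a random
#' permutation applied before a stable sort, so no donor is favoured by its
#' position in the data.
#'
#' @param query numeric score vector (length `M`) of the subject with
#'   missing outcome.
#' @param donors numeric matrix of donor score rows (length-`M` columns).
#' @param w weight vector of length `M`.
#' @param nn donor-pool size (positive integer, at most `nrow(donors)`).
#' @return Integer vector of `nn` donor row indices.
#' @export
donor_set <- function(query, donors, w, nn) {
  w <- check_weights(w)
  donors <- as.matrix(donors)
  nd <- nrow(donors)
  nn <- as.integer(nn)
  if (nn < 1L) stop("nn must be >= 1", call. = FALSE)
  if (nd < nn) stop("fewer donors than nn", call. = FALSE)
  d <- distance_matrix(matrix(query, 1L), donors, w)[1L, ]
  select_nn(d, nn)
}

# nn indices of smallest distances; random permutation before a stable sort
# breaks ties at the cut-off without positional bias.
select_nn <- function(d, nn) {
  perm <- sample.int(length(d))
  perm[order(d[perm], method = "radix")][seq_len(nn)]
}

#' Nearest-neighbour multiple imputation of a categorical outcome
#'
#' Bootstrap-proper nearest-neighbour multiple imputation. Each of the `K`
#' imputation rounds: (1) draws a with-replacement bootstrap sample of size
#' `n` from the full dataset (missing values included); (2) refits the
#' outcome working model on the bootstrap complete cases and the propensity
#' model on the whole bootstrap sample — a draw whose complete cases cannot
#' support the fits is redrawn (at most `max_redraws` times); (3) evaluates
#' the `M` raw predictive scores for the original-data subjects with missing
#' outcome (the queries, at their own covariates) and for the bootstrap
#' subjects with observed outcome (the donors; a subject resampled twice is
#' two donors), standardizing each score column jointly over the union of
#' queries and donors; (4) imputes each missing outcome by drawing uniformly
#' from its `nn`-nearest donor pool under the weighted score distance; and
#' (5) records the completed outcome vector with per-category estimates
#' `n_m / n` and Bernoulli standard errors `sqrt(p (1 - p) / n)`.
#'
#' @param data an [incomplete_data] object.
#' @param outcome_spec [working_model_spec] for the outcome (`"mlr"` or
#'   `"clr"`).
#' @param propensity_spec [working_model_spec] for the missingness indicator.
#' @param w weight vector of length `M` (see [check_weights()]).
#' @param nn donor-pool size; default 5.
#' @param K number of imputations (>= 2); default 10.
#' @param seed optional integer seed for reproducibility.
#' @param max_redraws bootstrap redraw limit for degenerate samples.
#' @return An object of class `imputation_result`: list with `completed`
#'   (n x K matrix of completed outcomes), `est` and `se` (K x M
#'   per-imputation estimates and Bernoulli SEs), `K`, `nn`, `w`, `M`,
#'   `method`, `seed`.
#' @seealso [rubin_combine()] to pool the `K` per-imputation estimates.
#' @export
nnmi_impute <- function(data, outcome_spec, propensity_spec, w,
                        nn = 5L, K = 10L, seed = NULL, max_redraws = 100L) {
  stopifnot(inherits(data, "incomplete_data"))
  w <- check_weights(w)
  if (length(w) != data$M) stop("length(w) must equal M", call. = FALSE)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  set_seed_if_given(seed)
  n <- data$n
  miss <- which(data$delta == 0L)
  method <- paste0("nnmi_", outcome_spec$family)

  completed <- matrix(rep(data$Y, K), n, K)
  if (length(miss)) {
    for (k in seq_len(K)) {
      imp <- with_redraws(function(attempt) {
        idx <- sample.int(n, n, replace = TRUE)
        boot <- incomplete_data(data$X[idx, , drop = FALSE], data$Y[idx], M = data$M)
        om <- fit_outcome_model(boot, outcome_spec)
        pm <- fit_propensity_model(boot, propensity_spec)
        donor_rows <- idx[boot$delta == 1L]
        if (length(donor_rows) < nn) degenerate_fit("fewer donors than nn")
        # raw M-column scores: queries from the ORIGINAL data, donors from
        # the bootstrap sample
        raw_q <- cbind(outcome_scores(om, data$X[miss, , drop = FALSE]),
                       propensity_scores(pm, data$X[miss, , drop = FALSE]))
        raw_d <- cbind(outcome_scores(om, data$X[donor_rows, , drop = FALSE]),
                       propensity_scores(pm, data$X[donor_rows, , drop = FALSE]))
        std <- standardize_scores(rbind(raw_q, raw_d))
        nq <- length(miss)
        s_q <- std$scores[seq_len(nq), , drop = FALSE]
        s_d <- std$scores[-seq_len(nq), , drop = FALSE]
        donor_y <- data$Y[donor_rows]
        D <- distance_matrix(s_q, s_d, w)
        vapply(seq_len(nq), function(i) {
          pool <- select_nn(D[i, ], nn)
          donor_y[pool[sample.int(nn, 1L)]]
        }, integer(1))
      }, max_redraws)
      completed[miss, k] <- imp
    }
  }
  est <- t(apply(completed, 2L, function(y) tabulate(y, data$M) / n))
  se <- sqrt(est * (1 - est) / n)
  structure(
    list(completed = completed, est = est, se = se, K = K, nn = nn, w = w,
         M = data$M, n = n, method = method, seed = seed),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("%s: K = %d imputations, n = %d, M = %d\n",
              x$method, x$K, x$n, x$M))
  cat("per-imputation estimate means:",
      paste(sprintf("%.4f", colMeans(x$est)), collapse = " "), "\n")
  invisible(x)
}

#' Combine per-imputation estimates with Rubin's rules
#'
#' Pools the `K` per-imputation category proportions: the point estimate is
#' their mean and the squared standard error is the mean within-imputation
#' variance plus `(1 + 1/K)` times the between-imputation variance,
#' `SE^2 = (1/K) sum_k s_k^2 + (1 + 1/K) (1/(K-1)) sum_k (P_k - Pbar)^2`.
#' Confidence intervals are Wald intervals truncated to `[0, 1]`.
#'
#' @param result an `imputation_result` from [nnmi_impute()] or
#'   [pmi_impute()].
#' @param level confidence level (default 0.95).
#' @return A `cat_estimate` data frame: one row per category with columns
#'   `category`, `est`, `se`, `lower`, `upper`.
#' @examples
#' r <- structure(list(est = rbind(0.3, 0.5), se = rbind(0.1, 0.1), K = 2,
#'                     M = 1, n = 100, method = "toy"),
#'                class = "imputation_result")
#' rubin_combine(r)$se  # sqrt(0.01 + 1.5 * 0.02) = 0.2
#' @export
rubin_combine <- function(result, level = 0.95) {
  stopifnot(inherits(result, "imputation_result"))
  K <- result$K
  if (K < 2L) stop("K must be >= 2 to estimate between-imputation variance",
                   call. = FALSE)
  pbar <- colMeans(result$est)
  within <- colMeans(result$se^2)
  between <- apply(result$est, 2L, stats::var)
  se <- sqrt(within + (1 + 1 / K) * between)
  z <- stats::qnorm(1 - (1 - level) / 2)
  cat_estimate(pbar, se,
               lower = pmax(0, pbar - z * se),
               upper = pmin(1, pbar + z * se),
               method = result$method, n_eff = result$n)
}

# Shared container for per-category estimates.
cat_estimate <- function(est, se, lower, upper, method, n_eff) {
  out <- data.frame(category = seq_along(est), est = est, se = se,
                    lower = lower, upper = upper, row.names = NULL)
  attr(out, "method") <- method
  attr(out, "n_eff") <- n_eff
  class(out) <- c("cat_estimate", "data.frame")
  out
}

#' @export
print.cat_estimate <- function(x, ...) {
  cat(sprintf("%s estimates (n_eff = %s)\n",
              attr(x, "method"), attr(x, "n_eff")))
  print.data.frame(round(as.data.frame(x), 4))
  invisible(x)
}
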