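#' Working-model specification
#'
#' Describes one of the three auxiliary regression models the imputation and
#' calibration machinery is built on: a baseline-category multinomial logistic
#' regression for the outcome (`"mlr"`), a set of `M - 1` cumulative logistic
#' regressions fitted without a proportional-odds constraint (`"clr"`), or a
#' binary regression for the missingness indicator (`"propensity"`).
#'
#' Outcome working models are logit-link only; the propensity model admits
#' either the logit or the probit link. Fits include an intercept by default;
#' `intercept = FALSE` reproduces intercept-free generating models exactly.
#'
#' @param family one of `"mlr"`, `"clr"`, `"propensity"`.
#' @param covariates integer indices into the columns of `X` used as
#'   predictors (the covariate subset of the working model).
#' @param link `"logit"` or `"probit"`; outcome families require `"logit"`.
#' @param intercept logical; include an intercept term.
#' @return An object of class `wm_spec`.
#' @examples
#' working_model_spec("mlr", covariates = 1:5)
#' working_model_spec("propensity", covariates = 1:3, link = "probit")
#' @export
working_model_spec <- function(family = c("mlr", "clr", "propensity"),
                               covariates,
                               link = "logit",
                               intercept = TRUE) {
  family <- match.arg(family)
  covariates <- as.integer(covariates)
  if (!length(covariates) || anyNA(covariates) || any(covariates < 1L) ||
      anyDuplicated(covariates)) {
    stop("covariates must be non-empty, unique, positive indices", call. = FALSE)
  }
  link <- match.arg(link, c("logit", "probit"))
  if (family %in% c("mlr", "clr") && link != "logit") {
    stop("outcome working models support the logit link only", call. = FALSE)
  }
  structure(
    list(family = family, covariates = covariates, link = link,
         intercept = isTRUE(intercept)),
    class = "wm_spec"
  )
}

#' @export
print.wm_spec <- function(x, ...) {
  cat(sprintf("working model: %s, link = %s, covariates = {%s}%s\n",
              toupper(x$family), x$link,
              paste(x$covariates, collapse = ","),
              if (x$intercept) ", with intercept" else ", no intercept"))
  invisible(x)
}

# Design matrix for a spec (intercept column first when requested).
model_matrix_for <- function(spec, X) {
  if (max(spec$covariates) > ncol(X)) {
    stop("covariate index exceeds ncol(X)", call. = FALSE)
  }
  mm <- X[, spec$covariates, drop = FALSE]
  if (spec$intercept) mm <- cbind(`(Intercept)` = 1, mm)
  mm
}

new_fitted_wm <- function(spec, coefficients, converged, loglik, M, n_fit) {
  structure(
    list(spec = spec, coefficients = coefficients, converged = converged,
         loglik = loglik, M = M, n_fit = n_fit),
    class = "fitted_wm"
  )
}

#' @export
print.fitted_wm <- function(x, ...) {
  cat(sprintf("fitted %s working model (%s), n = %d, logLik = %.2f%s\n",
              toupper(x$spec$family), x$spec$link, x$n_fit, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Binary ML fit on matrices; raises a degenerate-fit condition on
# non-convergence or (near-)separation so bootstrap drivers can redraw.
fit_binary <- function(mm, y, link) {
  fam <- stats::binomial(link = link)
  fit <- suppressWarnings(stats::glm.fit(
    mm, y, family = fam,
    control = stats::glm.control(epsilon = 1e-8, maxit = 200)
  ))
  co <- fit$coefficients
  if (!fit$converged || anyNA(co) || any(!is.finite(co)) || max(abs(co)) > 50) {
    degenerate_fit("binary regression did not converge (possible separation)")
  }
  list(coefficients = co, loglik = -fit$deviance / 2)
}

#' Fit the outcome working model
#'
#' Maximum-likelihood fit of the outcome working model on the complete cases
#' (subjects with observed `Y`). For family `"mlr"` this is one
#' baseline-category multinomial logistic regression with category 1 as the
#' reference; for `"clr"` it is `M - 1` separately fitted binary logistic
#' regressions of the indicator `I(Y > m)` on the covariate subset
#' (no proportional-odds constraint is imposed).
#'
#' A sample whose complete cases lack a level required by the family (all `M`
#' levels for `"mlr"`; both sides of every cut for `"clr"`) raises a
#' degenerate-fit condition, which bootstrap drivers treat as a signal to
#' redraw.
#'
#' @param data an [incomplete_data] object.
#' @param spec a [working_model_spec] with family `"mlr"` or `"clr"`.
#' @return A `fitted_wm` object whose `coefficients` matrix has `M - 1` rows
#'   (MLR row m: category m+1 versus category 1; CLR row m: cut at m).
#' @export
fit_outcome_model <- function(data, spec) {
  stopifnot(inherits(data, "incomplete_data"), inherits(spec, "wm_spec"))
  if (!spec$family %in% c("mlr", "clr")) {
    stop("spec$family must be 'mlr' or 'clr'", call. = FALSE)
  }
  cc <- complete_cases(data)
  if (!length(cc)) degenerate_fit("no complete cases")
  Y <- data$Y[cc]
  M <- data$M
  present <- sort(unique(Y))
  if (length(present) < 2L) {
    degenerate_fit("fewer than two outcome levels among complete cases")
  }
  mm <- model_matrix_for(spec, data$X)[cc, , drop = FALSE]
  q <- ncol(mm)
  if (spec$family == "mlr") {
    if (length(present) < M) {
      degenerate_fit("a level required by the multinomial fit is absent")
    }
    df <- data.frame(.y = factor(Y, levels = seq_len(M)))
    df <- cbind(df, as.data.frame(mm[, colnames(mm) != "(Intercept)", drop = FALSE]))
    form <- if (spec$intercept) .y ~ . else .y ~ . - 1
    fit <- nnet::multinom(form, data = df, trace = FALSE,
                          maxit = 200, reltol = 1e-8)
    if (fit$convergence != 0) {
      degenerate_fit("multinomial fit did not converge")
    }
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1, dimnames = list("2", names(co)))
    # reorder columns to match the spec's design-matrix order
    co <- co[, colnames(mm), drop = FALSE]
    if (max(abs(co)) > 50) degenerate_fit("multinomial fit near separation")
    new_fitted_wm(spec, co, TRUE, -fit$deviance / 2, M, length(cc))
  } else {
    co <- matrix(NA_real_, M - 1L, q, dimnames = list(NULL, colnames(mm)))
    ll <- 0
    for (m in seq_len(M - 1L)) {
      ind <- as.integer(Y > m)
      if (!any(ind == 0L) || !any(ind == 1L)) {
        degenerate_fit(sprintf("cumulative cut %d has a single class", m))
      }
      b <- fit_binary(mm, ind, "logit")
      co[m, ] <- b$coefficients
      ll <- ll + b$loglik
    }
    new_fitted_wm(spec, co, TRUE, ll, M, length(cc))
  }
}

#' Fit the missingness-propensity working model
#'
#' Maximum-likelihood binary regression of the missingness indicator `delta`
#' on the covariate subset, fitted on all `n` subjects (`delta` is always
#' observed).
#'
#' @param data an [incomplete_data] object.
#' @param spec a [working_model_spec] with family `"propensity"`.
#' @return A `fitted_wm` object with a single-row coefficient matrix.
#' @export
fit_propensity_model <- function(data, spec) {
  stopifnot(inherits(data, "incomplete_data"), inherits(spec, "wm_spec"))
  if (spec$family != "propensity") {
    stop("spec$family must be 'propensity'", call. = FALSE)
  }
  d <- data$delta
  if (all(d == d[1L])) degenerate_fit("missingness indicator has no variation")
  mm <- model_matrix_for(spec, data$X)
  b <- fit_binary(mm, d, spec$link)
  co <- matrix(b$coefficients, nrow = 1, dimnames = list(NULL, colnames(mm)))
  new_fitted_wm(spec, co, TRUE, b$loglik, data$M, data$n)
}

#' Outcome predictive scores
#'
#' The `M - 1` per-subject predictive scores of the outcome working model,
#' evaluated from its fitted coefficients at arbitrary covariate rows. For an
#' MLR fit, column m is the baseline-normalized probability score
#' `exp(eta_m) / (1 + sum_j exp(eta_j))` (the fitted probability of category
#' m+1); together with the implied baseline term the row sums to one. For a
#' CLR fit, column m is the inverse logit of the m-th cumulative linear
#' predictor, with no cross-column constraint.
#'
#' @param model a `fitted_wm` from [fit_outcome_model()].
#' @param X_rows numeric matrix of covariate rows (full covariate matrix; the
#'   model's covariate subset is extracted internally).
#' @return Numeric matrix, `nrow(X_rows)` by `M - 1`, entries in (0, 1).
#' @export
outcome_scores <- function(model, X_rows) {
  stopifnot(inherits(model, "fitted_wm"))
  if (!model$spec$family %in% c("mlr", "clr")) {
    stop("model is not an outcome working model", call. = FALSE)
  }
  mm <- model_matrix_for(model$spec, X_rows)
  eta <- clip_eta(mm %*% t(model$coefficients))
  if (model$spec$family == "mlr") {
    ex <- exp(eta)
    ex / (1 + rowSums(ex))
  } else {
    stats::plogis(eta)
  }
}

# Full M-column fitted category probabilities of an MLR fit (category 1 first).
mlr_category_probs <- function(model, X_rows) {
  stopifnot(model$spec$family == "mlr")
  mm <- model_matrix_for(model$spec, X_rows)
  ex <- exp(clip_eta(mm %*% t(model$coefficients)))
  denom <- 1 + rowSums(ex)
  cbind(1 / denom, ex / denom)
}

#' Missingness-propensity predictive score
#'
#' Per-row fitted probability of the outcome being observed,
#' `pi(X) = g^{-1}(X beta)`, under the propensity working model's link.
#'
#' @inheritParams outcome_scores
#' @return Numeric vector in (0, 1).
#' @export
propensity_scores <- function(model, X_rows) {
  stopifnot(inherits(model, "fitted_wm"))
  if (model$spec$family != "propensity") {
    stop("model is not a propensity working model", call. = FALSE)
  }
  mm <- model_matrix_for(model$spec, X_rows)
  drop(link_inverse(model$spec$link)(mm %*% t(model$coefficients)))
}

#' Standardize predictive-score columns
#'
#' Centres and scales each column to mean zero and sample standard deviation
#' one over the reference rows, returning the transform so it can be applied
#' to further rows. A column with standard deviation below `1e-12`
#' (an uninformative score) is set to zero with a warning: it then
#' contributes nothing to any distance, which matches its information
#' content.
#'
#' @param raw numeric matrix of raw scores (>= 2 rows) defining the
#'   reference distribution, or any matrix when `center`/`scale` are given.
#' @param center,scale optional transform to reuse (as returned in
#'   `$center` / `$scale`); when supplied, the columns are transformed with
#'   these constants instead of statistics of `raw`.
#' @return List with `scores` (standardized matrix), `center`, `scale`.
#' @examples
#' standardize_scores(cbind(c(1, 2, 3)))$scores
#' @export
standardize_scores <- function(raw, center = NULL, scale = NULL) {
  raw <- as.matrix(raw)
  if (is.null(center)) {
    if (nrow(raw) < 2L) stop("need >= 2 rows to standardize", call. = FALSE)
    center <- colMeans(raw)
    scale <- apply(raw, 2L, stats::sd)
  }
  degen <- scale < 1e-12
  if (any(degen)) {
    warning(sum(degen), " score column(s) with zero variance standardized to 0",
            call. = FALSE)
  }
  sc <- sweep(raw, 2L, center, `-`)
  sc <- sweep(sc, 2L, ifelse(degen, 1, scale), `/`)
  sc[, degen] <- 0
  list(scores = sc, center = center, scale = scale)
}
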