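#' Incomplete categorical-outcome dataset
#'
#' Bundles a fully observed covariate matrix `X`, a partially observed
#' categorical outcome `Y` with levels `1..M`, and the missingness indicator
#' `delta` (1 when `Y` is observed, 0 when it is missing). `delta` is derived
#' from `Y`: it is 0 exactly where `Y` is `NA`. All estimation and imputation
#' functions in the package consume this container.
#'
#' @param X numeric matrix (n subjects by p covariates) with no missing
#'   entries. A data frame of numeric columns is accepted and converted.
#' @param Y integer-valued vector of length n with entries in `1..M` or `NA`
#'   for missing outcomes.
#' @param M number of outcome categories; defaults to `max(Y, na.rm = TRUE)`.
#' @return An object of class `incomplete_data`: a list with elements `X`,
#'   `Y`, `delta`, `M`, `n`, `p`.
#' @examples
#' d <- incomplete_data(matrix(rnorm(8), 4, 2), c(1, 2, NA, 3), M = 3)
#' d$delta
#' @export
incomplete_data <- function(X, Y, M = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("X must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(X)) stop("covariates must be fully observed (X contains NA)", call. = FALSE)
  n <- nrow(X)
  if (n < 1L) stop("need at least one subject", call. = FALSE)
  if (length(Y) != n) stop("length(Y) must equal nrow(X)", call. = FALSE)
  Y <- as.integer(round(Y))
  obs <- Y[!is.na(Y)]
  if (length(obs) && any(obs < 1L)) {
    stop("Y levels must be positive integers 1..M", call. = FALSE)
  }
  if (is.null(M)) {
    if (!length(obs)) stop("all Y missing; supply M explicitly", call. = FALSE)
    M <- max(obs)
  }
  M <- as.integer(M)
  if (M < 2L) stop("M must be >= 2", call. = FALSE)
  if (length(obs) && any(obs > M)) {
    stop("observed Y level exceeds M", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  structure(
    list(X = X, Y = Y, delta = as.integer(!is.na(Y)), M = M,
         n = n, p = ncol(X)),
    class = "incomplete_data"
  )
}

#' @export
print.incomplete_data <- function(x, ...) {
  cat(sprintf(
    "incomplete_data: n = %d subjects, p = %d covariates, M = %d categories\n",
    x$n, x$p, x$M))
  cat(sprintf("  observed outcome: %d (%.1f%% missing)\n",
              sum(x$delta), 100 * mean(x$delta == 0)))
  tab <- tabulate(x$Y[x$delta == 1L], x$M)
  cat("  observed level counts:", paste(tab, collapse = " "), "\n")
  invisible(x)
}

complete_cases <- function(data) which(data$delta == 1L)

#' Number of complete cases
#' @param data an [incomplete_data] object.
#' @return Integer count of subjects with observed outcome.
#' @export
n_complete <- function(data) sum(data$delta)
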