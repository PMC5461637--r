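#' Read an incomplete dataset from CSV
#'
#' Reads a comma-delimited file with a header row, maps the outcome column
#' to integer levels `1..M`, and treats any outcome cell matching one of the
#' `missing_codes` (after trimming whitespace) as missing. Covariate columns
#' must be fully observed and numeric; a missing or non-numeric covariate
#' cell is a hard error naming the row and column. The label-to-level
#' mapping (sorted label order unless `level_order` is given) is attached as
#' attribute `level_map`.
#'
#' @param path CSV file path.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names.
#' @param missing_codes character values treated as missing in the outcome
#'   (default empty string and `"NA"`).
#' @param level_order optional character vector fixing the order in which
#'   outcome labels map to levels `1..M` (the first label becomes the MLR
#'   reference category).
#' @param M optional number of categories (defaults to the number of
#'   distinct observed labels).
#' @return An [incomplete_data] object with attribute `level_map`.
#' @export
read_incomplete_csv <- function(path, outcome, covariates,
                                missing_codes = c("", "NA"),
                                level_order = NULL, M = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!nrow(df)) stop("empty dataset", call. = FALSE)
  missing_cols <- setdiff(c(outcome, covariates), names(df))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (outcome %in% covariates) {
    stop("outcome column must be distinct from covariates", call. = FALSE)
  }
  X <- matrix(NA_real_, nrow(df), length(covariates),
              dimnames = list(NULL, covariates))
  for (j in seq_along(covariates)) {
    raw <- trimws(df[[covariates[j]]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | raw == "")
    if (length(bad)) {
      stop(sprintf("missing or non-numeric covariate value at row %d, column '%s'",
                   bad[1L], covariates[j]), call. = FALSE)
    }
    X[, j] <- val
  }
  ylab <- trimws(df[[outcome]])
  ylab[ylab %in% missing_codes] <- NA_character_
  observed_labels <- sort(unique(ylab[!is.na(ylab)]))
  if (!length(observed_labels)) stop("all outcome values missing", call. = FALSE)
  if (is.null(level_order)) {
    level_order <- observed_labels
  } else {
    unknown <- setdiff(observed_labels, level_order)
    if (length(unknown)) {
      stop("unknown outcome level code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  Y <- match(ylab, level_order)
  data <- incomplete_data(X, Y, M = if (is.null(M)) length(level_order) else M)
  attr(data, "level_map") <- stats::setNames(seq_along(level_order), level_order)
  data
}

#' Write an incomplete dataset to CSV
#'
#' Inverse of [read_incomplete_csv()]: writes covariates plus the outcome
#' column, rendering missing outcomes with `missing_code` and mapping levels
#' back through `level_map` when present.
#'
#' @param data an [incomplete_data] object.
#' @param path output CSV path.
#' @param outcome outcome column name.
#' @param missing_code string used for missing outcomes.
#' @param Y optional replacement outcome vector (e.g. a completed vector).
#' @return The path, invisibly.
#' @export
write_incomplete_csv <- function(data, path, outcome = "Y",
                                 missing_code = "NA", Y = NULL) {
  if (is.null(Y)) Y <- data$Y
  lm <- attr(data, "level_map")
  ylab <- if (is.null(lm)) as.character(Y) else names(lm)[Y]
  ylab[is.na(ylab)] <- missing_code
  df <- data.frame(data$X, check.names = FALSE)
  df[[outcome]] <- ylab
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a configured imputation analysis and write its outputs
#'
#' End-to-end tool entry point: reads the input CSV, runs the configured
#' imputation method (`"nnmi_mlr"`, `"nnmi_clr"`, or `"pmi"`), and writes to
#' `out_dir`: one completed dataset per imputation
#' (`imputation_01.csv`, ...), a combined-estimates table
#' (`estimates.csv`: category label, estimate, SE, 95% CI), and a JSON run
#' manifest (`manifest.json`: seed, package version, configuration, level
#' mapping, convergence diagnostics). Reruns with the same configuration and
#' seed produce identical outputs.
#'
#' @param config a named list with elements `input`, `outcome`,
#'   `covariates`; optional `missing_codes`, `level_order`, `method`
#'   (default `"nnmi_mlr"`), `outcome_covariates` / `propensity_covariates`
#'   (names, default all covariates), `weights` (default equal outcome
#'   weights with 0.2 on the propensity score), `nn` (5), `K` (10), `seed`
#'   (1), `out_dir` (required).
#' @return Invisibly, a list with the combined `estimates`, the
#'   `imputation_result`, and the output `paths`.
#' @export
run_impute <- function(config) {
  req <- c("input", "outcome", "covariates", "out_dir")
  if (!all(req %in% names(config))) {
    stop("config must name: ", paste(req, collapse = ", "), call. = FALSE)
  }
  method <- match.arg(config$method %||% "nnmi_mlr",
                      c("nnmi_mlr", "nnmi_clr", "pmi"))
  data <- read_incomplete_csv(config$input, config$outcome, config$covariates,
                              config$missing_codes %||% c("", "NA"),
                              config$level_order)
  M <- data$M
  seed <- as.integer(config$seed %||% 1L)
  K <- as.integer(config$K %||% 10L)
  nn <- as.integer(config$nn %||% 5L)
  oc <- match(config$outcome_covariates %||% config$covariates, config$covariates)
  pc <- match(config$propensity_covariates %||% config$covariates, config$covariates)
  if (anyNA(oc) || anyNA(pc)) {
    stop("working-model covariates must be a subset of `covariates`", call. = FALSE)
  }
  w <- check_weights(config$weights %||%
                       c(rep(0.8 / (M - 1), M - 1), 0.2))
  if (length(w) != M) stop("weights must have length M", call. = FALSE)
  ospec <- working_model_spec(if (method == "nnmi_clr") "clr" else "mlr", oc)
  pspec <- working_model_spec("propensity", pc)
  imp <- if (method == "pmi") {
    pmi_impute(data, ospec, K = K, seed = seed)
  } else {
    nnmi_impute(data, ospec, pspec, w, nn = nn, K = K, seed = seed)
  }
  comb <- rubin_combine(imp)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in seq_len(K)) {
    p <- file.path(config$out_dir, sprintf("imputation_%02d.csv", k))
    write_incomplete_csv(data, p, config$outcome, Y = imp$completed[, k])
    paths <- c(paths, p)
  }
  lm <- attr(data, "level_map")
  est_df <- data.frame(level = names(lm)[comb$category],
                       as.data.frame(comb), check.names = FALSE)
  est_path <- file.path(config$out_dir, "estimates.csv")
  utils::write.csv(est_df, est_path, row.names = FALSE)
  manifest <- list(
    package = "nnmicat",
    version = as.character(utils::packageVersion("nnmicat")),
    method = method, seed = seed, K = K, nn = nn, weights = w,
    outcome = config$outcome, covariates = config$covariates,
    outcome_covariates = config$covariates[oc],
    propensity_covariates = config$covariates[pc],
    missing_codes = config$missing_codes %||% c("", "NA"),
    level_map = as.list(lm),
    n = data$n, n_complete = n_complete(data)
  )
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(estimates = comb, imputation = imp,
                 paths = c(paths, est_path, man_path)))
}

#' Run a simulation scenario from a configuration file
#'
#' Reads a YAML (or JSON) scenario configuration, validates it, runs
#' [run_scenario()], and writes to `out_dir`: the aggregated results table
#' (`simulation_results.csv`), the generator-calibration report
#' (`calibration.csv`), and a JSON manifest with the full configuration and
#' seed. Recognized keys mirror the arguments of [scenario_config()], plus
#' `out_dir`, `truth_n_mc`, `calibration_n_mc`, and `calibrate`
#' (default `TRUE`).
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @return Invisibly, the `simulation_result`.
#' @export
run_simulation <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config must name out_dir", call. = FALSE)
  weights <- config$weights %||% list(c(0.4, 0.4, 0.2))
  if (!is.list(weights)) weights <- list(weights)
  cfg <- scenario_config(
    scenario = config$scenario %||% 0L,
    n = config$n %||% 400L,
    R = config$R %||% 500L,
    methods = config$methods %||% c("fo", "cc", "ce", "pmi",
                                    "nnmi_mlr", "nnmi_clr"),
    weights = lapply(weights, as.numeric),
    nn = config$nn %||% 5L,
    K = config$K %||% 10L,
    ce_B = config$ce_B %||% 200L,
    outcome_link = config$outcome_link,
    miss_model = config$miss_model %||% "M1",
    miss_link = config$miss_link,
    interpretation = config$interpretation %||% "softmax",
    seed = config$seed %||% 1L
  )
  res <- run_scenario(cfg, truth_n_mc = config$truth_n_mc %||% 1e6)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res),
                   file.path(config$out_dir, "simulation_results.csv"),
                   row.names = FALSE)
  if (isTRUE(config$calibrate %||% TRUE)) {
    cal <- calibrate_generator(cfg$outcome_link,
                               n_mc = config$calibration_n_mc %||% 1e6,
                               seed = cfg$seed)
    utils::write.csv(cal$report, file.path(config$out_dir, "calibration.csv"),
                     row.names = FALSE)
  }
  manifest <- c(unclass(cfg), list(truth = attr(res, "truth"),
                                   dropped = attr(res, "dropped")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
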