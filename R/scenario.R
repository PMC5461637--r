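#' Scenario configuration for the simulation study
#'
#' Encodes one cell of the simulation design: generating links and
#' missingness model, the working-model covariate subsets (full set, or the
#' reduced `{X1, X2, X3}` misspecification), methods, weight grid, and run
#' sizes. The five classical misspecification patterns are expressed through
#' `scenario`:
#' \describe{
#'   \item{0}{both working models correctly specified;}
#'   \item{1}{outcome working model reduced to 3 covariates;}
#'   \item{2}{propensity working model reduced to 3 covariates;}
#'   \item{3}{outcome generated with the probit link (working link logit);}
#'   \item{4}{missingness generated with the probit link (working link
#'     logit);}
#'   \item{5}{both generated with the probit link (working links logit).}
#' }
#' Working outcome models are always logit (MLR or CLR); the working
#' propensity model is always logit. Explicit `outcome_covs` / `prop_covs` /
#' link arguments override the scenario defaults.
#'
#' @param scenario integer 0..5.
#' @param n sample size per replicate (default 400).
#' @param R number of Monte Carlo replicates (default 500).
#' @param methods character subset of
#'   `c("fo", "cc", "ce", "pmi", "nnmi_mlr", "nnmi_clr")`.
#' @param weights list of length-3 weight vectors for the NNMI methods.
#' @param nn,K donor-pool size and number of imputations.
#' @param ce_B bootstrap replicates for the CE standard error; 0 skips the
#'   SE (CE then reports point estimates only, without coverage).
#' @param outcome_link,miss_link generating links; `miss_model` `"M1"`/`"M2"`.
#' @param outcome_covs,prop_covs working-model covariate subsets.
#' @param interpretation generator normalization (see
#'   [outcome_probabilities()]).
#' @param seed master seed; replicate seeds are derived from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = 0L, n = 400L, R = 500L,
                            methods = c("fo", "cc", "ce", "pmi",
                                        "nnmi_mlr", "nnmi_clr"),
                            weights = list(c(0.4, 0.4, 0.2),
                                           c(0.1, 0.7, 0.2),
                                           c(0.7, 0.1, 0.2)),
                            nn = 5L, K = 10L, ce_B = 200L,
                            outcome_link = NULL, miss_model = "M1",
                            miss_link = NULL,
                            outcome_covs = NULL, prop_covs = NULL,
                            interpretation = "softmax", seed = 1L) {
  scenario <- as.integer(scenario)
  stopifnot(scenario %in% 0:5, n >= 50L, R >= 1L)
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("fo", "cc", "ce", "pmi",
                                   "nnmi_mlr", "nnmi_clr"))
  weights <- lapply(weights, check_weights)
  if (is.null(outcome_link)) outcome_link <- if (scenario %in% c(3L, 5L)) "probit" else "logit"
  if (is.null(miss_link)) miss_link <- if (scenario %in% c(4L, 5L)) "probit" else "logit"
  if (is.null(outcome_covs)) outcome_covs <- if (scenario == 1L) 1:3 else 1:5
  if (is.null(prop_covs)) prop_covs <- if (scenario == 2L) 1:3 else 1:5
  structure(
    list(scenario = scenario, n = as.integer(n), R = as.integer(R),
         methods = methods, weights = weights, nn = as.integer(nn),
         K = as.integer(K), ce_B = as.integer(ce_B),
         outcome_link = outcome_link, miss_model = miss_model,
         miss_link = miss_link, outcome_covs = outcome_covs,
         prop_covs = prop_covs, interpretation = interpretation,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

method_weight_grid <- function(config) {
  rows <- list()
  for (m in config$methods) {
    if (m %in% c("nnmi_mlr", "nnmi_clr")) {
      for (w in config$weights) {
        rows[[length(rows) + 1L]] <- list(method = m, w = w)
      }
    } else {
      rows[[length(rows) + 1L]] <- list(method = m, w = NULL)
    }
  }
  rows
}

estimate_label <- function(method, w) {
  if (is.null(w)) method else
    sprintf("%s(%s)", method, paste(format(w, trim = TRUE), collapse = ","))
}

# One replicate: returns a data frame (method row x category) of est/se/cover.
run_replicate <- function(config, truth, rep_seed) {
  set.seed(rep_seed)
  sim <- simulate_dataset(config$n, config$outcome_link, config$miss_model,
                          config$miss_link, config$interpretation)
  data <- sim$data
  mlr_spec <- working_model_spec("mlr", config$outcome_covs)
  clr_spec <- working_model_spec("clr", config$outcome_covs)
  prop_spec <- working_model_spec("propensity", config$prop_covs, link = "logit")
  out <- list()
  for (cell in method_weight_grid(config)) {
    est <- switch(cell$method,
      fo = fo_estimate(sim$Y_full, M = 3L),
      cc = cc_estimate(data),
      ce = ce_estimate(data, mlr_spec, prop_spec, se_B = config$ce_B),
      pmi = rubin_combine(pmi_impute(data, mlr_spec, K = config$K)),
      nnmi_mlr = rubin_combine(nnmi_impute(data, mlr_spec, prop_spec,
                                           cell$w, nn = config$nn,
                                           K = config$K)),
      nnmi_clr = rubin_combine(nnmi_impute(data, clr_spec, prop_spec,
                                           cell$w, nn = config$nn,
                                           K = config$K))
    )
    out[[length(out) + 1L]] <- data.frame(
      label = estimate_label(cell$method, cell$w),
      method = cell$method,
      weights = if (is.null(cell$w)) NA_character_ else
        paste(cell$w, collapse = ","),
      category = est$category,
      est = est$est, se = est$se,
      cover = as.numeric(est$lower <= truth[est$category] &
                         truth[est$category] <= est$upper))
  }
  do.call(rbind, out)
}

#' Run one simulation scenario
#'
#' Generates `R` independent datasets from the configured generators and
#' applies every configured method to the same data within each replicate,
#' then aggregates per method and category: EST (mean estimate), SD
#' (empirical standard deviation of the estimates), SE (mean estimated
#' standard error), CR (coverage rate of the nominal 95% interval against
#' the generator truth), and the corresponding Monte Carlo errors. The
#' truth is computed by Monte Carlo from the selected generator (see
#' [true_marginals()]) unless supplied.
#'
#' Replicates aborted by the degenerate-fit redraw policy are dropped and
#' counted; more than 1% dropped fails the run.
#'
#' @param config a [scenario_config()].
#' @param truth optional length-3 truth vector (computed if `NULL`).
#' @param truth_n_mc Monte Carlo size for the truth (default 1e7).
#' @return A `simulation_result` data frame (label, method, weights,
#'   category, est, sd, se, cr, mce_est, mce_sd, mce_cr) with attributes
#'   `truth`, `R`, `dropped`, `config`.
#' @export
run_scenario <- function(config, truth = NULL, truth_n_mc = 1e7) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- derive_seeds(config$seed, config$R + 1L)
  if (is.null(truth)) {
    truth <- as.numeric(true_marginals(config$outcome_link,
                                       config$interpretation,
                                       n_mc = truth_n_mc,
                                       seed = seeds[config$R + 1L]))
  }
  reps <- vector("list", config$R)
  dropped <- 0L
  for (r in seq_len(config$R)) {
    reps[[r]] <- tryCatch(
      run_replicate(config, truth, seeds[r]),
      error = function(e) {
        if (grepl("degenerate fit persisted", conditionMessage(e))) NULL
        else stop(e)
      })
    if (is.null(reps[[r]])) dropped <- dropped + 1L
  }
  if (dropped > 0.01 * config$R) {
    stop(sprintf("%d of %d replicates dropped (> 1%% ceiling)",
                 dropped, config$R), call. = FALSE)
  }
  all_reps <- do.call(rbind, reps)
  R_done <- config$R - dropped
  agg <- do.call(rbind, lapply(
    split(all_reps, list(all_reps$label, all_reps$category), drop = TRUE),
    function(d) data.frame(
      label = d$label[1L], method = d$method[1L], weights = d$weights[1L],
      category = d$category[1L],
      est = mean(d$est), sd = stats::sd(d$est),
      se = mean(d$se), cr = mean(d$cover))
  ))
  agg <- agg[order(match(agg$label, unique(all_reps$label)), agg$category), ]
  rownames(agg) <- NULL
  attr(agg, "truth") <- truth
  attr(agg, "R") <- R_done
  attr(agg, "dropped") <- dropped
  attr(agg, "config") <- config
  class(agg) <- c("simulation_result", "data.frame")
  monte_carlo_errors(agg)
}

#' Monte Carlo errors of the simulation metrics
#'
#' Standard Monte Carlo error formulas over `R` replicates:
#' `MCE(EST) = SD / sqrt(R)`, `MCE(SD) = SD / sqrt(2 (R - 1))`,
#' `MCE(CR) = sqrt(CR (1 - CR) / R)`.
#'
#' @param result a `simulation_result` from [run_scenario()] (or any data
#'   frame with `sd` and `cr` columns and an `R` attribute).
#' @return The result with `mce_est`, `mce_sd`, `mce_cr` columns
#'   (re)computed.
#' @export
monte_carlo_errors <- function(result) {
  R <- attr(result, "R")
  if (is.null(R) || R < 2L) stop("result must carry R >= 2", call. = FALSE)
  result$mce_est <- result$sd / sqrt(R)
  result$mce_sd <- result$sd / sqrt(2 * (R - 1))
  result$mce_cr <- sqrt(result$cr * (1 - result$cr) / R)
  result
}

#' @export
print.simulation_result <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "simulation scenario %d: n = %d, R = %d (%d dropped), %s outcome / %s %s missingness\n",
    cfg$scenario, cfg$n, attr(x, "R"), attr(x, "dropped"),
    cfg$outcome_link, cfg$miss_model, cfg$miss_link))
  cat("truth:", paste(sprintf("%.4f", attr(x, "truth")), collapse = " "), "\n")
  print.data.frame(cbind(x[, c("label", "category")],
                         round(x[, c("est", "sd", "se", "cr")], digits)))
  invisible(x)
}
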