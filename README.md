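# nnmicat

Doubly robust nearest-neighbour multiple imputation (NNMI) for a
missing-at-random categorical outcome with `M >= 2` levels, for estimating
the marginal distribution `Pr(Y = m)`. Incomplete multi-level outcomes —
self-rated health, satisfaction scales, risk strata — are ubiquitous in
public-health data; complete-case proportions are biased whenever the
missingness and the outcome share covariates, and model-based imputation
stands or falls with its outcome model. NNMI hedges between the two.

## The method

Two working models are fitted from fully observed covariates `X`:

- an **outcome model** for `Y` on the complete cases — either one
  baseline-category multinomial logistic regression
  (`log Pr(Y=m)/Pr(Y=1) = α_m' X_O`, scores
  `Z_m = exp(α_m'X_O) / (1 + Σ_j exp(α_j'X_O))`) or `M−1` unconstrained
  cumulative logistic regressions (`Z_m = logit⁻¹(α_m' X_O)`);
- a **missingness model** for `δ = I(Y observed)` on all subjects, with
  score `Z_M = g⁻¹(β' X_δ)` (logit or probit `g`).

The `M` scores are standardized and combined into the weighted distance

    d(i, j) = sqrt( Σ_m ω_m [S_m(i) − S_m(j)]² ),   ω_m ≥ 0, Σ ω_m = 1.

Each missing outcome is imputed by a uniform draw from its `NN` nearest
observed-outcome donors; the working models are refitted on a bootstrap
resample before every imputation round so the procedure is proper, and the
`K` completed-data proportions are pooled with Rubin's rules:

    SE²(P̄) = (1/K) Σ_k s²(k) + (1 + 1/K) · (1/(K−1)) Σ_k (P(k) − P̄)².

Because the distance uses both working models, a sound missingness model
can rescue a misspecified outcome model (and vice versa) — a nonparametric
analogue of the doubly robust calibration estimator, but markedly more
stable when estimated missingness probabilities approach 0 or 1. The
package also implements the comparators: fully observed (FO), complete
case (CC), the calibration estimator (CE) with bootstrap SEs, and
parametric multiple imputation (PMI), plus the full Monte Carlo harness
(bias, empirical/estimated SE, coverage, Monte Carlo errors) that
evaluates them.

## Worked example

```r
library(nnmicat)

sim <- simulate_dataset(400, seed = 1)   # study generator, ~50% missing
sim$data
#> incomplete_data: n = 400 subjects, p = 5 covariates, M = 3 categories
#>   observed outcome: 204 (49.0% missing)
#>   observed level counts: 91 79 34

cc_estimate(sim$data)                     # complete cases: biased
#> cc estimates (n_eff = 204)
#>   category    est     se  lower  upper
#> 1        1 0.4461 0.0348 0.3779 0.5143
#> 2        2 0.3873 0.0341 0.3204 0.4541
#> 3        3 0.1667 0.0261 0.1155 0.2178

imp <- nnmi_impute(sim$data,
                   working_model_spec("mlr", 1:5),
                   working_model_spec("propensity", 1:5),
                   w = c(0.4, 0.4, 0.2), nn = 5, K = 10, seed = 2)
rubin_combine(imp)
#> nnmi_mlr estimates (n_eff = 400)
#>   category    est     se  lower  upper
#> 1        1 0.3755 0.0303 0.3161 0.4349
#> 2        2 0.2962 0.0358 0.2261 0.3664
#> 3        3 0.3282 0.0338 0.2620 0.3945
```

The pre-masking proportions in this dataset are (0.350, 0.283, 0.368): the
complete-case estimate overstates category 1 by ~0.10 and its interval
excludes the target, while NNMI recovers all three proportions within its
(Rubin-pooled) intervals. The weights `(0.4, 0.4, 0.2)` put 0.2 on the
propensity score — a small non-zero propensity weight is the recommended
default.

File-based workflows: `read_incomplete_csv()` / `run_impute()` /
`run_simulation()`, or the `inst/cli/nnmicat` script
(`impute`, `estimate`, `simulate` subcommands; see
`inst/extdata/example_scenario.yaml`).

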