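---
title: "Nearest-neighbour multiple imputation for categorical outcomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nearest-neighbour multiple imputation for categorical outcomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnmicat)
```

## The estimation problem

A categorical outcome $Y \in \{1, \dots, M\}$ is observed only for part of a
sample; covariates $X = (X_1, \dots, X_p)$ are fully observed, and the
missingness indicator $\delta$ ($1$ = observed) depends on $X$ but not on the
unobserved $Y$ — missing at random. The target is the marginal distribution
$\Pr(Y = m)$, $m = 1, \dots, M$. Complete-case proportions are biased
whenever $Y$ and $\delta$ share covariates; purely model-based imputation is
only as good as its outcome model. The package's core method uses *two*
working models, so that information from the missingness process can
compensate for defects in the outcome model.

## Working models and predictive scores

Two families of outcome working models are fitted on the complete cases:

* **MLR** — one baseline-category (multinomial) logistic regression with
  category 1 as reference,
  $\log \{\Pr(Y = m)/\Pr(Y = 1)\} = \alpha_m^\top X_O$ for $m = 2, \dots, M$.
  Its $M - 1$ predictive scores are the fitted probabilities
  $Z_m = e^{\alpha_m^\top X_O} / (1 + \sum_j e^{\alpha_j^\top X_O})$.
* **CLR** — $M - 1$ *separately fitted* binary logistic regressions of
  $I(Y > m)$ on $X_O$ (no proportional-odds constraint), each contributing
  the score $Z_m = \mathrm{logit}^{-1}(\alpha_m^\top X_O)$.

A binary regression of $\delta$ on $X_\delta$ (logit or probit link) gives
the propensity score $Z_M = \widehat{\Pr}(\delta = 1 \mid X)$.

The $M$ scores are standardized (mean 0, SD 1) and combined into a weighted
Euclidean distance
$d(i, j) = \sqrt{\sum_m \omega_m \{S_m(i) - S_m(j)\}^2}$ with
$\omega_m \ge 0$, $\sum \omega_m = 1$. Weights express trust in the working
models: $\omega_M = 0$ is pure predictive-score matching,
$\omega = (0, \dots, 0, 1)$ pure propensity matching — both supported for
sensitivity analysis.

## The imputation algorithm

Each of $K$ rounds: (1) bootstrap the full dataset (missing rows included);
(2) refit both working models on the bootstrap sample (outcome model on its
complete cases); (3) score the *original* subjects with missing $Y$ (queries)
and the *bootstrap* subjects with observed $Y$ (donors — a subject resampled
twice is two donors); (4) impute each query by a uniform draw from its $NN$
nearest donors; (5) record completed-data proportions $n_m/n$ with Bernoulli
standard errors. The bootstrap refit propagates parameter uncertainty, which
is what makes Rubin's combining rules
$$\mathrm{SE}^2(\bar P_m) = \tfrac1K \sum_k s_m^2(k) +
  \left(1 + \tfrac1K\right) \tfrac1{K-1} \sum_k \{P_m(k) - \bar P_m\}^2$$
valid for the pooled estimates.

## Comparator estimators

* **FO** — proportions of the pre-masking outcome (simulation benchmark).
* **CC** — complete-case proportions.
* **CE** — the calibration (augmented inverse-probability-weighting)
  estimator
  $\widehat P_m = n^{-1} \sum_i \widehat P_{i,m} +
   n^{-1} \sum_i \delta_i \widehat\pi(X_i)^{-1} (I_{i,m} - \widehat P_{i,m})$,
  doubly robust but not range-respecting, with bootstrap standard errors
  (both models refitted per resample).
* **PMI** — parametric MI: bootstrap, refit the MLR, draw each missing level
  from its predicted category distribution, pool with Rubin's rules.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nn` | 5 | donor-pool size; larger pools trade variance for bias |
| `K` | 10 | imputations; 10 suffices at ~50% missingness for these targets |
| `w` | — | score weights; a non-zero propensity weight (e.g. 0.2) is recommended |
| `se_B` | 200 | bootstrap resamples for the CE standard error |
| intercept | on | working models include an intercept (the generators have none; an intercept-free switch supports exact recovery checks) |

## The synthetic-data generator

The simulation harness draws $X_1, \dots, X_5 \sim U(-1, 1)$ i.i.d., a
three-category outcome from two linear predictors
$\eta_1 = X_1 - X_2 + 2X_3 - 2X_4 + 5X_5$ and
$\eta_2 = 2X_1 - 2X_2 + 3X_3 - 3X_4 + 1.5X_5$, and masks the outcome with
one of two logistic/probit missingness designs,
M1 $= 0.5X_1 - X_2 + X_3 - X_4 + X_5$ (probabilities mostly away from 0/1)
and M2 $= 0.5X_1 + 2X_2 - 4X_3 - 2X_4 + 2X_5$ (U-shaped, extreme). Both give
about 50% missingness by symmetry. Misspecification scenarios either drop
$X_4, X_5$ from a working model or generate with the probit link while the
working models keep the logit link.

**Normalizing the outcome generator.** Writing the generator as
$\Pr(Y = 1) = g^{-1}(\eta_1)$, $\Pr(Y = 2) = g^{-1}(\eta_2)$,
$\Pr(Y = 3) = 1 - p_1 - p_2$ does not define a valid probability model:
with these coefficients $p_1 + p_2 > 1$ for about half of all covariate
draws. `outcome_probabilities()` therefore implements two candidate
normalizations — the baseline-category multinomial ("softmax"), and the
literal reading with proportional renormalization of $(p_1, p_2)$ when they
exceed 1 — and `calibrate_generator()` compares their Monte Carlo marginals
with reference values for each link. *Neither candidate reproduces the
reference marginals* (the calibration report shows the achieved values);
`calibrate_generator()` surfaces this instead of patching it, and errors in
strict mode. An extensive search over alternative normalizations
(rejection, clipping, stick-breaking, cumulative readings, latent-utility
maxima, intercept-augmented variants) found none consistent with the full
set of reference quantities; indeed under the M2 design the reference
complete-case mean for category 2 has the opposite sign of bias from any
generator in which $\Pr(Y = 2 \mid X)$ increases in $\eta_2$, so the
reference values cannot all come from one generator of the stated form.

The package's default is the **softmax** normalization: it is the canonical
multinomial-logit model of which the per-category formulas are the standard
shorthand, and it makes the "correctly specified" scenarios exactly correct
(the generator *is* an MLR with reference category 1,
$\alpha_2 = \eta_2 - \eta_1$, $\alpha_3 = -\eta_1$). Coverage truths are
computed by large Monte Carlo from the selected generator
(`true_marginals()`, $10^7$ draws by default), never hard-coded, so
bias and coverage are internally consistent whatever normalization is
chosen. Cross-generator location comparisons with externally published
means inherit the normalization discrepancy; scale and stability
comparisons (SD inflation of CE under M2, NNMI's partial bias correction
under a misspecified outcome model) are robust to it.

What the generator does *not* emulate: correlated or non-uniform
covariates, measurement error, missingness depending on unobservables
(MNAR), covariate missingness, or survey weights. Passing tests demonstrate
correctness of the algorithms under MAR with fully observed covariates, not
performance on data violating those assumptions.

## Numerical choices

* Linear predictors are clipped to $\pm 35$ before exponentiation
  (saturation point of the inverse links at double precision), identically
  everywhere.
* ML fits use relative log-likelihood tolerance $10^{-8}$, at most 200
  iterations; non-convergence or near-separation ($|\hat\beta| > 50$)
  raises a typed degenerate-fit condition.
* A bootstrap draw whose complete cases cannot support the outcome fit (a
  missing level for MLR, a one-sided cut for CLR, fewer donors than `nn`)
  is redrawn, at most 100 times, after which the replicate aborts; the
  simulation harness drops and counts aborted replicates and fails if more
  than 1% drop.
* Scores are standardized over the *union* of query and donor rows within
  each bootstrap round, so both sides of every distance share one scale; a
  zero-variance score column standardizes to zero (it carries no
  information) with a warning.
* Ties at the `nn`-th distance are broken by a seeded random permutation
  applied before a stable sort — no positional bias, full reproducibility.
* CE weights invert $\widehat\pi$ clipped to $[10^{-6}, 1]$; no aggressive
  truncation, so the estimator's instability under extreme missingness
  probabilities remains visible (the clip count is reported).
* Confidence intervals are Wald intervals, truncated to $[0, 1]$ for
  range-respecting estimators; CE intervals are not truncated.

## Open design points, resolved

* Working models include an intercept by default; the generators are
  intercept-free, and recovery checks verify the fitted intercepts vanish.
* For the probit-missingness scenario the *working* propensity model keeps
  the logit link (the generating link is probit) — link misspecification
  lives in the generator.
* PMI draws imputations stochastically from the predicted category
  probabilities (modal assignment would void Rubin's between-imputation
  variance) and bootstraps before each refit.
* The CE bootstrap refits both working models per resample.

## Problem sizes used by the reproduction checks

The packaged checks run the fully-observed and complete-case comparisons at
$R = 500$ replicates of $n = 400$, the calibration estimator at $R = 200$,
parametric MI at $R = 150$, and the nearest-neighbour methods at
$R = 100$–$200$ with $K = 10$, `nn = 5`; mean-estimate comparisons use the
tolerance $\max(0.01,\ 3\,\mathrm{SD}/\sqrt{R})$ and SD comparisons 25%
relative. Parameter-recovery checks use a single dataset of $n = 50{,}000$.

## Limitations

* Outcome working models are logit-link only (probit appears in data
  generation and the propensity model); no proportional-odds or penalized
  fits.
* The donor-pool size is fixed, not adaptive; no caliper.
* Covariates must be fully observed; continuous outcomes and covariate
  imputation are out of scope.
* CE point estimates can fall outside $[0, 1]$ by construction.
```{r example, eval = FALSE}
sim <- simulate_dataset(400, seed = 1)
imp <- nnmi_impute(sim$data,
                   working_model_spec("mlr", 1:5),
                   working_model_spec("propensity", 1:5),
                   w = c(0.4, 0.4, 0.2), nn = 5, K = 10, seed = 2)
rubin_combine(imp)
```
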