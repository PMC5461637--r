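# Example simulation scenario for `nnmicat simulate` / run_simulation().
# Scenario 1: outcome working model reduced to X1..X3, propensity model
# correct; logit generators, non-extreme (M1) missingness.
scenario: 1
n: 400
R: 50
methods: [fo, cc, ce, pmi, nnmi_mlr]
weights:
  - [0.4, 0.4, 0.2]
  - [0.1, 0.7, 0.2]
nn: 5
K: 10
ce_B: 0
miss_model: M1
seed: 20260921
out_dir: scenario1_results
truth_n_mc: 1.0e6
calibrate: true
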