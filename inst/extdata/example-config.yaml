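# Example pipeline configuration for read_pipeline_config().
sim:
  n_patients: 500
  years: 4
  start_year: 2012
  encounter_rate: 1
  transfer_prob: 0.1
  missing_prob: 0.15
  repeat_prob: 0.1
  death_prob: 0.02
  seed: 1
  age_range: [20, 60]
  tests:
    - test_name: crp
      specimen: P
      unit: mg/L
      standard_ri: [0, 10]
      baseline_mean: 6
      baseline_sd: 4
      true_beta1: 0.8
      true_theta: 8
    - test_name: hgb
      specimen: B
      unit: mmol/L
      standard_ri: [7.4, 10.0]
      baseline_mean: 8.7
      baseline_sd: 0.9
      true_beta1: 0.6
      true_theta: 30
  outcomes:
    - code: I21
      intercept: -2.2
      weights: {crp: 1.3, hgb: -1.0}
      sex_weight: 0.4
      uses_seasonal_truth: true
cohort:
  min_patients: 50
seasonal:
  rule: amplitude_phase
model:
  families: [neural_net]
  n_search: 3
  cv_folds: 3
eval:
  n_boots: 200
  bca_boots: 2000
seed: 1
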