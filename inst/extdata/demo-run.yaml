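# Small end-to-end demonstration run: synthetic IRR cohort -> quartile
# incidence table and multivariate logistic model, plus a 30- vs 60-min
# infusion simulation with first-dose exposure metrics.
stages: [generate, irr, simulate, expose]
seed: 20
cohort:
  n_patients: 600
model:
  cl0_pop: 0.015
  v1_pop: 5.4
  q: 0.016
  v2_pop: 2.9
  emax: -0.2
  t50_days: 27
  gamma: 2
  omega_var_cl: 0.09
  omega_var_v1: 0.04
  omega_var_v2: 0.25
  omega_var_emax: 0.01
  omega_cov_cl_v1: 0.03
  omega_cov_cl_emax: 0.005
  sigma_add: 1
  sigma_prop: 0.2
scenario:
  dose_per_kg: 8
  schedule: Q2W
  n_cycles: 1
  n_subjects: 4
  durations_min: [30, 60]
analysis:
  rate_mode: observed
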