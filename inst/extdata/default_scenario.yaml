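n_participants: 145
arm_fractions:
  low: 0.333333333333333
  mod: 0.333333333333333
  high: 0.333333333333333
diets:
  low:
    carb: 0.2
    fat: 0.6
    protein: 0.2
  mod:
    carb: 0.4
    fat: 0.4
    protein: 0.2
  high:
    carb: 0.6
    fat: 0.2
    protein: 0.2
cim_slope: 62.5
covariates:
  female_p: 0.69
  age_meanlog: 3.575150688785593
  age_sdlog: 0.559
  weight_mean:
    female: 87.0
    male: 101.0
  weight_sd:
    female: 17.0
    male: 19.0
  height_mean:
    female: 163.5
    male: 178.0
  height_sd:
    female: 7.0
    male: 7.0
  insulin30_meanlog: 4.731802836921458
  insulin30_sdlog: 0.5838
  n_cohorts: 3
  runin_mean: 10.5
  runin_sd: 1.6
  race_p:
    white: 0.786
    black: 0.103
    asian: 0.034
    other: 0.077
  hispanic_p: 0.145
  body_fat_mean: 40.700000000000003
  body_fat_sd: 6.4
baseline_tee:
  intercept: 883.0
  male: 400.0
  per_kg: 15.0
  per_cm: 5.0
  per_year: -5.0
  resid_sd: 560.0
  reference: 3008.0
test_phase:
  drift_per_kcal: 0.4
  subject_sd: 100.0
  timepoint_effect: -30.0
  maintenance_sd: 0.0
errors:
  tee_sd: 150.0
  ei_sd: 120.0
  dfm_sd: 0.01
  underreport_kcal: -300.0
  underreport_scaling: 2.5
  intake_lag: 1.0
nonadherence:
  fraction: 0.0
  drift: 0.5
energetics:
  rho_fm: 9441.0
  weir_o2: 3.941
  weir_co2: 1.106
  fuel_rq:
    carb: 1.0
    fat: 0.71
    protein: 0.835
analysis:
  reference_weight: 82.0
  n_quantile_bins: 36
  max_excluded: 18
  covariates:
  - sex
  - age
  - weight
  - height
  - runin_loss
  - tee_base_meas
  - insulin30
  - cohort
missingness: 0.0
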