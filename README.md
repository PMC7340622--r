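# uebias

Simulation and analysis toolkit for a recurring trap in randomized feeding
trials: excluding participants *post hoc* on **Unaccounted Energy (UE)** —

```
UE = | energy intake − energy expenditure − ρ_fm · Δ fat mass |   (kcal/d)
```

— a post-randomization variable built from the same measured total energy
expenditure (TEE) as the trial outcome. In a three-arm carbohydrate feeding
trial (20/40/60% of energy, weight-loss maintenance), sequentially dropping
the highest-UE half of the cohort makes the low- vs high-carbohydrate TEE
effect appear to shrink. `uebias` makes the counter-argument executable:
because every component of UE carries size-dependent measurement error, and
because the doubly-labeled-water (DLW) error is shared between UE and the
outcome, exclusion on UE is exclusion on covariates and on measurement error
— confounding that covariate adjustment largely repairs.

The package is for biostatisticians and trial methodologists who want to
*measure* this selection bias on cohorts with known ground truth rather than
reason about it informally.

## What it provides

* `scenario_config()` — every generator and analysis parameter in one
  validated object (YAML/JSON round trip, unknown keys rejected).
* `sample_cohort()` / `apply_nonadherence()` — synthetic 145-person cohorts
  with latent truth: baseline covariates matched to the target trial's
  marginals, a programmed 250 kcal/d low-vs-high effect (62.5 kcal/d per 10
  percentage points of carbohydrate, normalized to 82 kg), DLW errors
  proportional to measured TEE, size-graded intake under-recording, and an
  RQ-mediated DLW bias for non-adherent eaters.
* `weir_energy_expenditure()`, `food_quotient()`, `rq_bias_ratio()` —
  closed-form DLW energetics.
* `add_unaccounted_energy()` — UE, its median split (73/72 at n = 145) and
  36 descending quantile bins.
* `fit_diet_effect()` — unadjusted and covariate-adjusted intention-to-treat
  estimates of the low-vs-high contrast on normalized TEE change
  (subject-mean OLS ≡ compound-symmetry repeated measures; GLS cross-check).
* `sequential_exclusion()`, `compare_extreme_groups()` — the exclusion sweep
  with within-estimator attenuation, and the UE-group-by-diet interaction
  test.
* `chi_squared_test()`, `pooled_t_test()`, `wilcoxon_rank_sum()`,
  `build_baseline_table()` — baseline-imbalance machinery.
* `nonadherence_sweep()`, `symmetric_tail_exclusion()`,
  `tail_depletion_diagnostic()` — the sensitivity suite.
* `run_pipeline()` plus `inst/scripts/uebias.R` — seeded end-to-end runs
  with a JSON reproducibility manifest; `autoplot()` methods for the result
  objects (curves only — no trend lines across dependent sweep points).

## A worked example

```r
library(uebias)
library(dplyr)

cfg <- scenario_config()
cohort <- sample_cohort(cfg, seed = 7) |> add_unaccounted_energy(cfg)

median(cohort$ue)
#> 298

fit_diet_effect(cohort, adjusted = TRUE, config = cfg)
#> Low- vs high-carbohydrate TEE effect (adjusted): 231.5 kcal/d (SE 52.6), p = 2.19e-05, n = 145
#>   covariates: sex, age, weight, height, runin_loss, tee_base_meas, log(insulin30), cohort
```

Both estimators recover the programmed 250 kcal/d effect on the full cohort
(the adjusted one here reads 231.5 ± 52.6). Now exclude the highest-UE
quantile bins, one at a time:

```r
sw <- sequential_exclusion(cohort, cfg)
sw[c(1, 10, 19), c("k_excluded", "n_retained", "estimate_unadjusted",
                   "estimate_adjusted", "attenuation_unadjusted",
                   "attenuation_adjusted")]
#>  k_excluded n_retained estimate_unadjusted estimate_adjusted att_unadj att_adj
#>           0        145               196.3               232     0.000   0.000
#>           9        109               183.8               245     0.064  -0.056
#>          18         73                36.4               169     0.815   0.270
autoplot(sw, what = "attenuation")
```

With half the cohort excluded the *unadjusted* estimate has lost 81% of the
full-cohort effect while the *adjusted* estimate has lost 27% — the bias is
mostly confounding, not adherence. The reason is visible in the baseline
table and the depletion diagnostic:

```r
build_baseline_table(cohort, c("sex", "weight", "tee_base_meas"))
#>  variable       low_ue                 high_ue                p_value
#>  sex            female 65 (89.0%)      female 41 (56.9%)      1.3e-05
#>  weight         85.6 (17.2)            95.2 (18.8)            1.6e-03
#>  tee_base_meas  2516.7 (531.7)         3458.4 (640.5)         3.0e-17

tail_depletion_diagnostic(cohort, config = cfg)
#> <tail_depletion> cor(|TEE error|, excluded) = 0.294; cor(signed) = 0.110; 72 excluded
```

The excluded half is more male, heavier, and ~940 kcal/d higher in baseline
TEE — and exclusion correlates with the latent DLW error itself. How much
non-adherence could the finding tolerate?

```r
sens <- nonadherence_sweep(cfg, replicates = 100, seed = 1)
max_significant_fraction(sens)
#> 0.7
```

Under conservative RQ assumptions the adjusted effect stays significant
across the whole 0–0.7 grid.

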