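test_that("step 0 reproduces the full-cohort fits with zero attenuation", {
  sw <- sequential_exclusion(cached_cohort, default_cfg, max_excluded = 3)
  full_adj <- fit_diet_effect(cached_cohort, TRUE, default_cfg)
  full_un <- fit_diet_effect(cached_cohort, FALSE, default_cfg)
  expect_equal(sw$estimate_adjusted[1], full_adj$estimate, tolerance = 1e-9)
  expect_equal(sw$estimate_unadjusted[1], full_un$estimate, tolerance = 1e-9)
  expect_identical(sw$attenuation_adjusted[1], 0)
  expect_identical(sw$attenuation_unadjusted[1], 0)
})

test_that("retained counts shrink strictly and bins stay frozen", {
  sw <- sequential_exclusion(cached_cohort, default_cfg)
  expect_equal(nrow(sw), 19)
  expect_true(all(diff(sw$n_retained) < 0))
  expect_true(sw$n_retained[19] %in% c(72L, 73L))  # half the cohort gone
  # frozen bins: step k retains exactly the participants with ue_bin > k
  expect_equal(sw$n_retained[6], sum(cached_cohort$ue_bin > 5))
})

test_that("exclusion on an independent random variable does not attenuate", {
  set.seed(61)
  atten <- vapply(1:80, function(r) {
    co <- random_bin_cohort(cached_cohort, default_cfg, seed = 6100 + r)
    sdat_full <- fit_diet_effect(co, TRUE, default_cfg)$estimate
    half <- fit_diet_effect(co[co$ue_bin > 18, ], TRUE, default_cfg)$estimate
    1 - half / sdat_full
  }, numeric(1))
  mc_se <- stats::sd(atten) / sqrt(length(atten))
  expect_lt(abs(mean(atten)), 3 * mc_se)
})

test_that("small cohorts degrade gracefully: undefined steps carry reasons", {
  cfg <- scenario_config(n_participants = 21,
                         analysis = list(n_quantile_bins = 10, max_excluded = 8))
  co <- add_unaccounted_energy(sample_cohort(cfg, seed = 62), cfg)
  sw <- sequential_exclusion(co, cfg)
  expect_equal(nrow(sw), 9)
  undefined <- is.na(sw$estimate_adjusted)
  expect_true(any(undefined))
  expect_true(all(!is.na(sw$reason[undefined])))
  expect_true(all(is.na(sw$reason[1])))
  # the sweep keeps going to the final step despite failures
  expect_equal(sw$k_excluded, 0:8)
})

test_that("sweeps require UE bins", {
  co <- sample_cohort(default_cfg, seed = 63)
  expect_error(sequential_exclusion(co, default_cfg), "ue_bin")
})

test_that("extreme-group comparison: interaction null is calibrated at 5%", {
  set.seed(64)
  pvals <- vapply(1:300, function(r) {
    co <- add_unaccounted_energy(
      sample_cohort(default_cfg, seed = sample.int(1e8, 1)), default_cfg)
    compare_extreme_groups(co, default_cfg)$p_interaction
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / length(pvals))
  expect_gt(frac, 0.05 - ci_half - 0.01)
  expect_lt(frac, 0.05 + ci_half + 0.01)
})

test_that("extreme-group comparison detects a group-confined effect", {
  set.seed(65)
  hits <- vapply(1:80, function(r) {
    co <- add_unaccounted_energy(
      sample_cohort(default_cfg, seed = sample.int(1e8, 1)), default_cfg)
    # erase the true diet effect (and its RQ-free measurement image) in the
    # high-UE half only: a 250 kcal/d group difference in the diet effect
    kill <- co$ue_group == "high"
    co$tee_test_meas_t1[kill] <- co$tee_test_meas_t1[kill] -
      co$diet_effect_true[kill]
    co$tee_test_meas_t2[kill] <- co$tee_test_meas_t2[kill] -
      co$diet_effect_true[kill]
    compare_extreme_groups(co, default_cfg)$p_interaction < 0.05
  }, logical(1))
  # simulated detection rate for a 250 kcal/d group-confined effect is ~0.42
  # at n = 145 under the default noise structure (300-replicate calibration):
  # far above the 5% null rate, bounded here with Monte-Carlo headroom
  expect_gt(mean(hits), 0.3)
})

test_that("degenerate single-group input is refused", {
  co <- cached_cohort
  co$ue_group <- factor("low", levels = c("low", "high"))
  expect_error(compare_extreme_groups(co, default_cfg), "both UE groups")
})
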