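test_that("cohorts have the contracted size, arms and internal consistency", {
  co <- cached_cohort
  expect_equal(nrow(co), 145)
  counts <- table(co$arm)
  expect_true(max(counts) - min(counts) <= 3)  # 1:1:1 within cohort blocks
  expect_true(all(co$weight > 0 & co$height > 0 & co$tee_base_true > 0))
  expect_equal(co$bmi, co$weight / (co$height / 100)^2, tolerance = 1e-9)
  # measured TEE decomposes into truth, RQ factor and stored error, row-wise
  expect_equal(co$tee_test_meas_t1,
               co$tee_test_true_t1 * co$rq_bias + co$tee_err_t1,
               tolerance = 1e-9)
  expect_equal(co$tee_test_meas_t2,
               co$tee_test_true_t2 * co$rq_bias + co$tee_err_t2,
               tolerance = 1e-9)
})

test_that("generation is byte-identical for a repeated (config, seed)", {
  a <- sample_cohort(default_cfg, seed = 99)
  b <- sample_cohort(default_cfg, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(default_cfg, seed = 100)))
})

test_that("with all measurement imperfections zeroed, measured equals true and UE is 0", {
  cfg <- zero_measurement_error(default_cfg)
  expect_warning(co <- add_unaccounted_energy(sample_cohort(cfg, seed = 5), cfg),
                 "tied")  # UE is identically zero, so the median split degenerates
  expect_equal(co$tee_test_meas_t1, co$tee_test_true_t1, tolerance = 1e-12)
  expect_equal(co$tee_base_meas, co$tee_base_true, tolerance = 1e-12)
  expect_equal(co$ei_meas, co$ei_true, tolerance = 1e-12)
  expect_equal(co$dfm_meas, co$dfm_true, tolerance = 1e-12)
  expect_equal(max(co$ue), 0, tolerance = 1e-9)
})

test_that("baseline measured TEE is calibrated to mean 3008 kcal/d", {
  means <- vapply(1:200, function(s) {
    mean(sample_cohort(default_cfg, seed = 7000 + s)$tee_base_meas)
  }, numeric(1))
  mc_se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 3008), 3 * mc_se + 2)
  # marginal SD near the 718 kcal/d target
  expect_equal(mean(vapply(1:50, function(s) {
    stats::sd(sample_cohort(default_cfg, seed = 7000 + s)$tee_base_meas)
  }, numeric(1))), 718, tolerance = 0.05)
})

test_that("randomization balances baseline covariates across arms", {
  vars <- c("age", "weight", "height", "tee_base_true", "insulin30")
  set.seed(55)
  std_diff <- replicate(500, {
    co <- sample_cohort(default_cfg, seed = sample.int(1e8, 1))
    low <- co[co$arm == "low", ]; high <- co[co$arm == "high", ]
    vapply(vars, function(v) {
      (mean(low[[v]]) - mean(high[[v]])) /
        stats::sd(c(low[[v]], high[[v]]))
    }, numeric(1))
  })
  expect_true(all(abs(rowMeans(std_diff)) < 0.05))
})

test_that("noise-free dose-response equals cim_slope x 4 exactly", {
  cfg <- deterministic_scenario(default_cfg)
  co <- sample_cohort(cfg, seed = 11)
  fit <- fit_diet_effect(co, adjusted = FALSE, config = cfg)
  expect_equal(fit$estimate, 4 * cfg$cim_slope, tolerance = 1e-9)
  # slope override propagates exactly
  cfg2 <- deterministic_scenario(scenario_config(cim_slope = 50))
  fit2 <- fit_diet_effect(sample_cohort(cfg2, seed = 11), FALSE, cfg2)
  expect_equal(fit2$estimate, 200, tolerance = 1e-9)
})

test_that("cohort CSV round trip is lossless to 1e-9", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cached_cohort, path)
  back <- read_cohort(path)
  expect_equal(back$tee_test_meas_t1, cached_cohort$tee_test_meas_t1,
               tolerance = 1e-9)
  expect_equal(back$ue, cached_cohort$ue, tolerance = 1e-9)
  expect_identical(as.character(back$arm), as.character(cached_cohort$arm))
})

test_that("invalid configs are refused by the generator", {
  cfg <- default_cfg
  cfg$errors$tee_sd <- -5  # bypass constructor, generator must re-validate
  expect_error(sample_cohort(cfg, seed = 1), "tee_sd")
})
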