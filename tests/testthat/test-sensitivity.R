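test_that("at zero non-adherence the sweep reduces to the plain effect estimate", {
  sens <- nonadherence_sweep(default_cfg, fractions = 0, replicates = 20,
                             seed = 71)
  tab <- as.data.frame(sens)
  # apparent and conservative estimators coincide when nothing is corrected
  expect_equal(tab$mean_estimate[tab$estimator == "apparent"],
               tab$mean_estimate[tab$estimator == "conservative"],
               tolerance = 1e-9)
  mc_se <- tab$mean_se[1] / sqrt(20)
  expect_lt(abs(tab$mean_estimate[1] - 250), 4 * mc_se)
})

test_that("the conservative estimate declines with the non-adherence fraction", {
  sens <- nonadherence_sweep(default_cfg, fractions = c(0, 0.3, 0.6),
                             replicates = 30, seed = 72)
  cons <- dplyr::filter(as.data.frame(sens), estimator == "conservative")
  slack <- 2 * sqrt(2) * mean(cons$mean_se) / sqrt(30)
  expect_true(all(diff(cons$mean_estimate) < slack))
  expect_lt(cons$mean_estimate[3], cons$mean_estimate[1])
  # the apparent estimator keeps carrying the RQ artifact and stays high
  app <- dplyr::filter(as.data.frame(sens), estimator == "apparent")
  expect_gt(app$mean_estimate[3], cons$mean_estimate[3])
})

test_that("sweep input validation", {
  expect_error(nonadherence_sweep(default_cfg, fractions = c(0, 1.5)), "\\[0, 1\\]")
  expect_error(nonadherence_sweep(default_cfg, replicates = 0), "replicates")
})

test_that("symmetric-tail exclusion: zero tails change nothing; both-tail
           exclusion preserves the effect while one-sided attenuates", {
  none <- symmetric_tail_exclusion(cached_cohort, 0, default_cfg)
  expect_equal(none$attenuation, 0, tolerance = 1e-12)
  expect_equal(none$n_retained, nrow(cached_cohort))

  set.seed(73)
  res <- vapply(1:60, function(r) {
    co <- sample_cohort(default_cfg, seed = 7300 + r)
    both <- symmetric_tail_exclusion(co, 0.15, default_cfg, side = "both")
    top <- symmetric_tail_exclusion(co, 0.15, default_cfg, side = "upper")
    c(both = both$attenuation, top = top$attenuation)
  }, numeric(2))
  # two-tail exclusion does not attenuate (paper direction: "not attenuated")
  expect_lt(mean(res["both", ]),
            2 * stats::sd(res["both", ]) / sqrt(ncol(res)))
  # matched one-sided exclusion attenuates more (paired comparison)
  d <- res["top", ] - res["both", ]
  expect_gt(mean(d), 2 * stats::sd(d) / sqrt(length(d)))
  expect_error(symmetric_tail_exclusion(cached_cohort, 0.5), "tail_fraction")
})

test_that("tail-depletion diagnostic: null under coin-flip exclusion,
           positive under UE exclusion, refusal without latent errors", {
  set.seed(74)
  null_corr <- vapply(1:100, function(r) {
    excl <- sample(c(TRUE, FALSE), nrow(cached_cohort), TRUE)
    tail_depletion_diagnostic(cached_cohort, excl, default_cfg)$cor_abs
  }, numeric(1))
  expect_lt(abs(mean(null_corr)),
            3 * stats::sd(null_corr) / sqrt(length(null_corr)))

  set.seed(75)
  pos <- vapply(1:50, function(r) {
    co <- add_unaccounted_energy(
      sample_cohort(default_cfg, seed = 7500 + r), default_cfg)
    tail_depletion_diagnostic(co, config = default_cfg)$cor_abs
  }, numeric(1))
  expect_gt(mean(pos > 0), 0.9)

  td <- tail_depletion_diagnostic(cached_cohort, config = default_cfg)
  expect_s3_class(td$trajectory, "tbl_df")
  expect_equal(nrow(td$trajectory), 19)
  stripped <- dplyr::select(cached_cohort, -tee_err_t1, -tee_err_t2)
  expect_error(tail_depletion_diagnostic(stripped, config = default_cfg),
               "unsupported")
})

test_that("retained-error trajectory drifts as the high-UE tail is depleted", {
  set.seed(76)
  tr <- lapply(1:30, function(r) {
    co <- add_unaccounted_energy(
      sample_cohort(default_cfg, seed = 7600 + r), default_cfg)
    tail_depletion_diagnostic(co, config = default_cfg)$trajectory
  })
  last <- vapply(tr, function(t) t$mean_abs_err_retained[19], numeric(1))
  first <- vapply(tr, function(t) t$mean_abs_err_retained[1], numeric(1))
  # retained |error| shrinks: exclusion eats the error tails
  expect_lt(mean(last), mean(first))
})
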