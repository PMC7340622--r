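test_that("chi-squared reproduces the printed count-based comparisons", {
  sex <- chi_squared_test(rbind(c(60, 13), c(40, 32)))
  expect_equal(round(sex$statistic, 2), 12.02)
  expect_equal(round(sex$p_value, 4), 0.0005)
  hispanic <- chi_squared_test(rbind(c(13, 60), c(8, 64)))
  expect_equal(round(hispanic$p_value, 4), 0.2519)
  race <- chi_squared_test(cbind(c(59, 5, 3, 6), c(55, 10, 2, 5)))
  expect_equal(race$df, 3)
  expect_equal(round(race$p_value, 4), 0.5537)
})

test_that("chi-squared edge behaviour: identical proportions, permutations, zero margins", {
  flat <- chi_squared_test(rbind(c(30, 60), c(10, 20)))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)
  tab <- rbind(c(12, 5, 9), c(3, 14, 6))
  a <- chi_squared_test(tab)
  b <- chi_squared_test(tab[, c(3, 1, 2)])
  c2 <- chi_squared_test(tab[c(2, 1), ])
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$statistic, c2$statistic, tolerance = 1e-12)
  expect_error(chi_squared_test(rbind(c(0, 0), c(5, 3))), "zero marginal")
  expect_error(chi_squared_test(matrix(1:3)), "2x2")
})

test_that("pooled t: frozen oracle for the weight row, summary/raw equivalence", {
  w <- pooled_t_test(87.1, 16.8, 73, 95.6, 18.9, 72)
  # frozen from direct evaluation of the pooled-variance formula
  expect_equal(w$statistic, -2.863205, tolerance = 1e-5)
  expect_equal(w$df, 143)
  expect_equal(w$p_value, 0.004825, tolerance = 1e-5)
  # identical summaries
  same <- pooled_t_test(5, 2, 10, 5, 2, 12)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # raw route equals summary route, and equals stats::t.test(var.equal)
  set.seed(51)
  x <- stats::rnorm(40, 10, 3); y <- stats::rnorm(35, 11, 2.5)
  raw <- pooled_t_test_raw(x, y)
  summ <- pooled_t_test(mean(x), stats::sd(x), 40, mean(y), stats::sd(y), 35)
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-9)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(raw$p_value, ref$p.value, tolerance = 1e-9)
  # degenerate zero-variance edge
  expect_equal(pooled_t_test(1, 0, 5, 2, 0, 5)$p_value, 0)
})

test_that("Wilcoxon: exact enumeration for small n, approximation close to exact", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)   # most extreme of the C(6,3) = 20 splits, doubled
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3) * 0 + 1)$p_value,
               wilcoxon_rank_sum(c(1, 2, 3), rep(1, 3))$p_value)
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  set.seed(52)
  for (i in 1:20) {
    x <- stats::rnorm(6); y <- stats::rnorm(6, 0.8)
    exact <- wilcoxon_rank_sum(x, y)$p_value
    expect_equal(exact, wilcoxon_exact_oracle(x, y), tolerance = 1e-9)
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(approx - exact), 0.02)
  }
})

test_that("baseline table renders every variable with the right dispatch", {
  tab <- build_baseline_table(cached_cohort)
  expect_equal(nrow(tab), 12)
  expect_setequal(tab$variable[tab$test == "wilcoxon"], c("age", "insulin30"))
  expect_setequal(tab$variable[tab$test == "chi-squared"],
                  c("race", "hispanic", "sex"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_warning(build_baseline_table(cached_cohort, c("weight", "nope")),
                 "nope")
  lines <- format_baseline_table(tab)
  expect_length(lines, 12)
  expect_match(lines[1], "p = 0\\.\\d{4}")
})

test_that("grouping by a coin flip is null-calibrated", {
  set.seed(53)
  pvals <- unlist(lapply(1:150, function(r) {
    co <- cached_cohort
    co$ue_group <- factor(sample(c("low", "high"), nrow(co), TRUE),
                          levels = c("low", "high"))
    tab <- build_baseline_table(co, c("age", "weight", "height", "bmi",
                                      "body_fat", "insulin30", "runin_loss"))
    tab$p_value
  }))
  expect_gt(mean(pvals < 0.05), 0.03)
  expect_lt(mean(pvals < 0.05), 0.07)
})

test_that("UE grouping shows the documented confounded imbalance pattern", {
  set.seed(54)
  stats_by <- replicate(30, {
    cfg <- default_cfg
    co <- add_unaccounted_energy(sample_cohort(cfg, sample.int(1e8, 1)), cfg)
    tab <- build_baseline_table(co, c("sex", "weight", "tee_base_meas"))
    high <- co$ue_group == "high"
    c(p_sex = tab$p_value[tab$variable == "sex"],
      p_weight = tab$p_value[tab$variable == "weight"],
      p_tee = tab$p_value[tab$variable == "tee_base_meas"],
      d_female = mean(co$sex[high] == "female") - mean(co$sex[!high] == "female"),
      d_weight = mean(co$weight[high]) - mean(co$weight[!high]),
      d_tee = mean(co$tee_base_meas[high]) - mean(co$tee_base_meas[!high]))
  })
  m <- rowMeans(stats_by)
  # high-UE half: fewer females, heavier, higher baseline TEE; tests significant
  expect_lt(m["p_sex"], 0.05)
  expect_lt(m["p_weight"], 0.05)
  expect_lt(m["p_tee"], 0.05)
  expect_lt(m["d_female"], 0)
  expect_gt(m["d_weight"], 0)
  expect_gt(m["d_tee"], 0)
})
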