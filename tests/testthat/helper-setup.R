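# Shared fixtures and independent oracles, built in code at test time.

default_cfg <- scenario_config()

# one default cohort with UE columns, reused by read-only tests
cached_cohort <- local({
  cfg <- scenario_config()
  add_unaccounted_energy(sample_cohort(cfg, seed = 424242), cfg)
})

# Exhaustive-enumeration oracle for the two-sample Wilcoxon test (no ties):
# every assignment of the pooled ranks to group 1 is equally likely under
# the null; two-sided p doubles the smaller tail including the observed U.
wilcoxon_exact_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(m + n, m)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  min(1, 2 * min(lower, upper))
}

# mean attenuation of a random (exclusion-independent-of-everything) sweep
random_bin_cohort <- function(cohort, cfg, seed) {
  set.seed(seed)
  cohort$ue_bin <- assign_quantile_bins(stats::runif(nrow(cohort)),
                                        cfg$analysis$n_quantile_bins,
                                        ids = cohort$id)
  cohort
}
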