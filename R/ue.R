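# Unaccounted Energy: |intake - expenditure - energy stored as body fat|,
# all measured over the test phase. The statistic mixes true non-adherence
# with every measurement error feeding energy balance, which is what makes
# excluding on it hazardous.

#' Unaccounted Energy for given intake, expenditure and fat-change values
#'
#' `UE = |ei - tee - rho_fm * dfm_rate|`. Inputs are test-phase
#' time-averaged values; `dfm_rate` is the fat-mass change per day so that
#' `rho_fm * dfm_rate` is the energy stored in (or released from) fat.
#'
#' @param ei Energy intake, kcal/d.
#' @param tee Total energy expenditure, kcal/d.
#' @param dfm_rate Fat-mass change, kg/d.
#' @param rho_fm Energy density of fat-mass change, kcal/kg (> 0).
#' @return UE, kcal/d (non-negative).
#' @examples
#' compute_ue(2000, 2300, -0.03, 9441)  # 16.77
#' @export
compute_ue <- function(ei, tee, dfm_rate, rho_fm = 9441) {
  if (rho_fm <= 0) stop("compute_ue: rho_fm must be > 0", call. = FALSE)
  abs(ei - tee - rho_fm * dfm_rate)
}

#' Median dichotomization into low/high UE groups
#'
#' Values at or below the sample median go to the low-UE group, values above
#' it to the high-UE group; with an odd sample size the median participant is
#' in the low group (so 145 participants split 73/72).
#'
#' @param ue_values Numeric vector of UE values (length >= 2).
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_by_median <- function(ue_values) {
  if (length(ue_values) < 2 || anyNA(ue_values)) {
    stop("dichotomize_by_median: need >= 2 non-missing values", call. = FALSE)
  }
  med <- stats::median(ue_values)
  grp <- factor(ifelse(ue_values <= med, "low", "high"), levels = c("low", "high"))
  if (all(grp == "low")) {
    warning("dichotomize_by_median: all values tied at the median; ",
            "high group is empty", call. = FALSE)
  }
  grp
}

#' Quantile bins by descending UE
#'
#' Ranks UE from highest (bin 1) to lowest (bin `n_bins`); bin sizes differ
#' by at most one. Ties are broken by the accompanying id (stable), so
#' binning is reproducible and permutation-invariant up to that rule.
#'
#' @param ue_values Numeric vector (length >= `n_bins`).
#' @param n_bins Number of quantile bins.
#' @param ids Tie-break ids; defaults to input order.
#' @return Integer bin per value, 1 = highest UE.
#' @export
assign_quantile_bins <- function(ue_values, n_bins = 36, ids = seq_along(ue_values)) {
  n <- length(ue_values)
  if (n < n_bins) {
    stop(sprintf("assign_quantile_bins: %d values cannot fill %d bins", n, n_bins),
         call. = FALSE)
  }
  ord <- order(-ue_values, ids)
  sizes <- diff(round(seq(0, n, length.out = n_bins + 1)))
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), sizes)
  bins
}

#' Add UE, quantile bin and median group to a cohort
#'
#' Computes per-participant UE from the measured, time-averaged test-phase
#' intake and expenditure and the measured fat-mass-change rate, then
#' attaches `ue`, `ue_bin` (1 = highest UE of `n_quantile_bins`) and
#' `ue_group` (median split).
#'
#' @param cohort Cohort tibble with measured energy columns.
#' @param config A [scenario_config()].
#' @return The cohort with `ue`, `ue_bin`, `ue_group` columns.
#' @examples
#' cohort <- sample_cohort(scenario_config(), seed = 1) |>
#'   add_unaccounted_energy(scenario_config())
#' table(cohort$ue_group)
#' @export
add_unaccounted_energy <- function(cohort, config) {
  stopifnot(inherits(config, "scenario_config"))
  need <- c("ei_meas", "tee_test_meas_t1", "tee_test_meas_t2", "dfm_meas")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("add_unaccounted_energy: cohort lacks measured columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tee_bar <- rowMeans(cbind(cohort$tee_test_meas_t1, cohort$tee_test_meas_t2),
                      na.rm = TRUE)
  cohort$ue <- compute_ue(cohort$ei_meas, tee_bar, cohort$dfm_meas,
                          config$energetics$rho_fm)
  cohort$ue_bin <- assign_quantile_bins(cohort$ue,
                                        config$analysis$n_quantile_bins,
                                        ids = cohort$id)
  cohort$ue_group <- dichotomize_by_median(cohort$ue)
  cohort
}
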