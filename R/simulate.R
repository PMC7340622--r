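# Synthetic feeding-trial cohorts. Each participant carries both the latent
# truth (true TEE trajectory, true intake, the realized measurement errors)
# and the measured surface an analyst would see, so selection bias induced by
# excluding on a measured quantity can be read off directly.
#
# Structure of a cohort draw:
#   1. design & baseline: covariates, enrollment cohort, randomized arm,
#      true baseline TEE from a linear size/sex/age model;
#   2. adherence: which participants drift toward the 40%-carbohydrate diet,
#      fixing consumed composition, true diet effect and true/assumed RQ;
#   3. measurement: DLW errors proportional to the TEE being measured, intake
#      records with size-graded under-recording plus the unrecorded
#      diet-induced provision change, fat-mass-change error.
# Stage 3 is re-derivable from stored standard-normal draws (z_* columns), so
# apply_nonadherence() can re-flag a cohort deterministically.

arm_levels <- c("low", "mod", "high")

#' Simulate a feeding-trial cohort
#'
#' Draws a complete cohort: randomized arm (1:1:1 within enrollment cohort),
#' baseline covariates matching the target trial's marginals, true baseline
#' and test-phase TEE (two timepoints with a shared subject intercept), true
#' intake at weight maintenance, and all measured quantities with their
#' latent error components.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; the draw is fully deterministic given
#'   `(config, seed)`.
#' @return A tibble with one row per participant. Measured columns end in
#'   `_meas`, latent truth in `_true`, realized random error components in
#'   `_err`, and standard-normal draws in `z_*`.
#' @examples
#' cohort <- sample_cohort(scenario_config(), seed = 1)
#' dplyr::count(cohort, arm)
#' @export
sample_cohort <- function(config, seed) {
  stopifnot(inherits(config, "scenario_config"))
  config <- validate_scenario(config)
  n <- config$n_participants
  cv <- config$covariates

  set.seed(as.integer(seed))
  cohort_id <- sample.int(cv$n_cohorts, n, replace = TRUE)
  arm <- allocate_arms(cohort_id, config$arm_fractions)

  sex <- factor(ifelse(stats::rbinom(n, 1, cv$female_p) == 1, "female", "male"),
                levels = c("female", "male"))
  is_male <- sex == "male"
  age <- stats::rlnorm(n, cv$age_meanlog, cv$age_sdlog)
  weight <- stats::rnorm(n, cv$weight_mean[ifelse(is_male, "male", "female")],
                         cv$weight_sd[ifelse(is_male, "male", "female")])
  weight <- pmax(weight, 45)
  height <- stats::rnorm(n, cv$height_mean[ifelse(is_male, "male", "female")],
                         cv$height_sd[ifelse(is_male, "male", "female")])
  height <- pmax(height, 130)
  insulin30 <- stats::rlnorm(n, cv$insulin30_meanlog, cv$insulin30_sdlog)
  runin_loss <- stats::rnorm(n, cv$runin_mean, cv$runin_sd)
  race <- factor(sample(names(cv$race_p), n, replace = TRUE, prob = cv$race_p),
                 levels = names(cv$race_p))
  hispanic <- stats::rbinom(n, 1, cv$hispanic_p) == 1
  body_fat <- stats::rnorm(n, cv$body_fat_mean, cv$body_fat_sd)

  bt <- config$baseline_tee
  tee_base_true <- bt$intercept + bt$male * is_male + bt$per_kg * weight +
    bt$per_cm * height + bt$per_year * age +
    stats::rnorm(n, 0, bt$resid_sd)
  tee_base_true <- pmax(tee_base_true, 800)
  s0 <- pmax(tee_base_true / bt$reference, 0.3)
  tee_base_meas <- tee_base_true + stats::rnorm(n) * config$errors$tee_sd * s0

  design <- tibble::tibble(
    id = seq_len(n),
    cohort = factor(cohort_id),
    arm = factor(arm, levels = arm_levels),
    sex, age, weight, height,
    bmi = weight / (height / 100)^2,
    body_fat, race, hispanic, insulin30, runin_loss,
    weight_postloss = weight * (1 - runin_loss / 100),
    tee_base_true, tee_base_meas,
    subj_intercept = stats::rnorm(n, 0, config$test_phase$subject_sd),
    maint_noise = stats::rnorm(n, 0, config$test_phase$maintenance_sd),
    u_nonadherence = stats::runif(n),
    z_tee_t1 = stats::rnorm(n),
    z_tee_t2 = stats::rnorm(n),
    z_ei = stats::rnorm(n),
    z_dfm = stats::rnorm(n),
    u_miss_t1 = stats::runif(n),
    u_miss_t2 = stats::runif(n)
  )
  apply_nonadherence(design, config)
}

# 1:1:1 restricted randomization within enrollment cohort.
allocate_arms <- function(cohort_id, arm_fractions) {
  arm <- character(length(cohort_id))
  for (co in unique(cohort_id)) {
    idx <- which(cohort_id == co)
    n_c <- length(idx)
    base <- floor(n_c * arm_fractions[arm_levels])
    rem <- n_c - sum(base)
    extra <- table(factor(sample(arm_levels, rem,
                                 prob = arm_fractions[arm_levels]),
                          levels = arm_levels))
    counts <- base + as.integer(extra)
    arm[idx] <- sample(rep(arm_levels, counts))
  }
  arm
}

#' Apply (or re-apply) the non-adherence mechanism and measurement model
#'
#' Flags `round(fraction * n_arm)` participants per arm as non-adherent
#' (those with the smallest stored uniform draw, so the flagging is
#' deterministic for a given cohort), moves their consumed composition
#' `drift` of the way toward 40% carbohydrate, recomputes the true diet
#' effect from the consumed diet, and rebuilds every measured quantity --
#' including the DLW bias that arises because expenditure is computed with
#' the prescribed diet's food quotient while the consumed diet sets the true
#' respiratory quotient.
#'
#' With `fraction = 0` the cohort is returned with all participants adherent
#' and measurements identical to a fresh [sample_cohort()] draw.
#'
#' @param cohort A cohort tibble from [sample_cohort()].
#' @param config A [scenario_config()]; its `nonadherence` block controls the
#'   flagging.
#' @return The cohort with adherence, consumed-diet, truth and measurement
#'   columns (re)computed.
#' @export
apply_nonadherence <- function(cohort, config) {
  stopifnot(inherits(config, "scenario_config"))
  need <- c("arm", "tee_base_true", "subj_intercept", "u_nonadherence",
            "z_tee_t1", "z_tee_t2", "z_ei", "z_dfm")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("apply_nonadherence: cohort lacks generator columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  frac <- config$nonadherence$fraction
  drift <- config$nonadherence$drift

  cohort$adherent <- TRUE
  for (a in arm_levels) {
    idx <- which(cohort$arm == a)
    k <- round(frac * length(idx))
    if (k > 0) {
      flagged <- idx[order(cohort$u_nonadherence[idx])[seq_len(k)]]
      cohort$adherent[flagged] <- FALSE
    }
  }

  prescribed <- t(vapply(as.character(cohort$arm),
                         function(a) unclass(config$diets[[a]]),
                         numeric(3)))
  carb_p <- prescribed[, "carb"]
  protein <- prescribed[, "protein"]
  carb_c <- ifelse(cohort$adherent, carb_p, carb_p + drift * (0.40 - carb_p))
  fat_c <- 1 - protein - carb_c

  fq <- config$energetics$fuel_rq
  rq_assumed <- carb_p * fq["carb"] + prescribed[, "fat"] * fq["fat"] +
    protein * fq["protein"]
  rq_true <- carb_c * fq["carb"] + fat_c * fq["fat"] + protein * fq["protein"]
  rq_bias <- rq_bias_ratio(rq_assumed, rq_true,
                           config$energetics$weir_o2, config$energetics$weir_co2)

  # true diet effect: anchored at the 40% reference diet, proportional to
  # post-weight-loss body size so the normalized (per 82 kg) effect is
  # homogeneous across participants
  an <- config$analysis
  delta <- config$cim_slope * (0.40 - carb_c) / 0.10 *
    cohort$weight_postloss / an$reference_weight

  tp <- config$test_phase
  bt <- config$baseline_tee
  tee_level <- cohort$tee_base_true +
    tp$drift_per_kcal * (cohort$tee_base_true - bt$reference) +
    delta + cohort$subj_intercept
  tee_t1 <- tee_level
  tee_t2 <- tee_level + tp$timepoint_effect
  tee_mean_true <- (tee_t1 + tee_t2) / 2

  er <- config$errors
  s_t1 <- pmax(tee_t1 / bt$reference, 0.3)
  s_t2 <- pmax(tee_t2 / bt$reference, 0.3)
  s_m <- pmax(tee_mean_true / bt$reference, 0.3)
  tee_err_t1 <- cohort$z_tee_t1 * er$tee_sd * s_t1
  tee_err_t2 <- cohort$z_tee_t2 * er$tee_sd * s_t2

  # energy balance: intake holds weight, so true fat-mass change only
  # reflects maintenance noise
  ei_true <- tee_mean_true + cohort$maint_noise
  dfm_true <- cohort$maint_noise / config$energetics$rho_fm
  ei_err <- cohort$z_ei * er$ei_sd
  ei_meas <- ei_true - er$intake_lag * delta +
    er$underreport_kcal * s_m^er$underreport_scaling + ei_err
  dfm_err <- cohort$z_dfm * er$dfm_sd
  dfm_meas <- dfm_true + dfm_err

  cohort <- dplyr::mutate(cohort,
    carb_prescribed = carb_p,
    carb_consumed = carb_c,
    fat_consumed = fat_c,
    protein_consumed = protein,
    rq_assumed = as.numeric(rq_assumed),
    rq_true = as.numeric(rq_true),
    rq_bias = as.numeric(rq_bias),
    diet_effect_true = delta,
    tee_test_true_t1 = tee_t1,
    tee_test_true_t2 = tee_t2,
    tee_err_t1 = tee_err_t1,
    tee_err_t2 = tee_err_t2,
    tee_test_meas_t1 = tee_t1 * rq_bias + tee_err_t1,
    tee_test_meas_t2 = tee_t2 * rq_bias + tee_err_t2,
    ei_true = ei_true,
    ei_err = ei_err,
    ei_meas = ei_meas,
    dfm_true = dfm_true,
    dfm_err = dfm_err,
    dfm_meas = dfm_meas
  )
  if (config$missingness > 0) {
    cohort$tee_test_meas_t1[cohort$u_miss_t1 < config$missingness] <- NA_real_
    cohort$tee_test_meas_t2[cohort$u_miss_t2 < config$missingness] <- NA_real_
  }
  cohort
}

#' Zero every measurement imperfection in a scenario
#'
#' Sets all random error SDs and the systematic recording biases
#' (under-recording, intake lag) to zero, so measured quantities equal the
#' latent truth exactly. Used for noise-free oracle checks.
#'
#' @param config A [scenario_config()].
#' @return The modified config.
#' @export
zero_measurement_error <- function(config) {
  scenario_config_update(config, errors = list(
    tee_sd = 0, ei_sd = 0, dfm_sd = 0,
    underreport_kcal = 0, intake_lag = 0
  ))
}

#' Remove biological between-subject variability from the test phase
#'
#' Combined with [zero_measurement_error()], this makes every participant's
#' outcome a deterministic function of the assigned arm and body size: the
#' subject-level intercept, the size-proportional maintenance drift and the
#' timepoint shift are all zeroed. The noise-free normalized low-vs-high
#' contrast then equals `4 * cim_slope` exactly for every draw, which is the
#' closed-form oracle for the dose-response.
#'
#' @param config A [scenario_config()].
#' @return The modified config.
#' @export
deterministic_scenario <- function(config = scenario_config()) {
  config <- zero_measurement_error(config)
  scenario_config_update(config, test_phase = list(
    drift_per_kcal = 0, subject_sd = 0, timepoint_effect = 0, maintenance_sd = 0
  ))
}

#' Update fields of an existing scenario
#'
#' @param config A `scenario_config`.
#' @param ... Overrides as in [scenario_config()].
#' @return The updated, re-validated config.
#' @export
scenario_config_update <- function(config, ...) {
  stopifnot(inherits(config, "scenario_config"))
  overrides <- list(...)
  cfg <- merge_config(unclass(config), overrides, path = "")
  validate_scenario(cfg)
}

#' Write / read a cohort as CSV
#'
#' Plain-CSV round trip of the cohort table (lossless to numerical printing
#' precision; factors restored from their level sets).
#'
#' @param cohort Cohort tibble.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$arm <- factor(df$arm, levels = arm_levels)
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("female", "male"))
  if ("cohort" %in% names(df)) df$cohort <- factor(df$cohort)
  if ("race" %in% names(df)) df$race <- factor(df$race)
  if ("ue_group" %in% names(df)) df$ue_group <- factor(df$ue_group, levels = c("low", "high"))
  tibble::as_tibble(df)
}
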