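# Diet-effect estimation: the low- vs high-carbohydrate contrast on
# normalized TEE change, with or without baseline-covariate adjustment.
# The repeated-measures model (two test timepoints, compound-symmetry
# within-subject covariance) reduces to an ordinary least-squares fit on
# subject means for balanced data; that equivalence is the default engine,
# with a generalized-least-squares fit available as a cross-check.

#' Normalize a TEE change to a reference body weight
#'
#' Expresses a kcal/d change as kcal/d per kg times a reference weight, so
#' that participants of different size are compared on a common scale:
#' `(delta_tee / weight_postloss) * reference_weight`.
#'
#' @param delta_tee TEE change, kcal/d.
#' @param weight_postloss Post-weight-loss body weight, kg (> 0).
#' @param reference_weight Reference weight, kg (> 0), default 82.
#' @return Normalized TEE change, kcal/d.
#' @examples
#' normalize_tee_change(300, 100, 82)  # 246
#' @export
normalize_tee_change <- function(delta_tee, weight_postloss, reference_weight = 82) {
  if (any(weight_postloss <= 0) || any(reference_weight <= 0)) {
    stop("normalize_tee_change: weights must be > 0", call. = FALSE)
  }
  delta_tee / weight_postloss * reference_weight
}

# Long (participant x timepoint) outcome table used by the gls engine.
effect_long_data <- function(cohort, config) {
  refw <- config$analysis$reference_weight
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, dplyr::any_of(c(
      "id", "arm", "sex", "age", "weight", "height", "runin_loss",
      "tee_base_meas", "insulin30", "cohort", "weight_postloss",
      "tee_test_meas_t1", "tee_test_meas_t2"))),
    cols = c("tee_test_meas_t1", "tee_test_meas_t2"),
    names_to = "timepoint", values_to = "tee_test_meas",
    names_pattern = "tee_test_meas_(t[12])"
  )
  long$timepoint <- factor(long$timepoint, levels = c("t1", "t2"))
  long$y <- normalize_tee_change(long$tee_test_meas - long$tee_base_meas,
                                 long$weight_postloss, refw)
  long[!is.na(long$y), ]
}

# Subject-level analysis table (outcome averaged over available timepoints).
# Plain column arithmetic: this is on the hot path of the replicate suites.
effect_subject_data <- function(cohort, config) {
  tee_bar <- rowMeans(cbind(cohort$tee_test_meas_t1, cohort$tee_test_meas_t2),
                      na.rm = TRUE)
  y <- normalize_tee_change(tee_bar - cohort$tee_base_meas,
                            cohort$weight_postloss,
                            config$analysis$reference_weight)
  dat <- data.frame(
    id = cohort$id, arm = cohort$arm, y = y,
    sex = cohort$sex, age = cohort$age, weight = cohort$weight,
    height = cohort$height, runin_loss = cohort$runin_loss,
    tee_base_meas = cohort$tee_base_meas, insulin30 = cohort$insulin30,
    cohort = cohort$cohort
  )
  extra <- setdiff(config$analysis$covariates, names(dat))
  for (v in intersect(extra, names(cohort))) dat[[v]] <- cohort[[v]]
  if ("ue_bin" %in% names(cohort)) dat$ue_bin <- cohort$ue_bin
  if ("ue_group" %in% names(cohort)) dat$ue_group <- cohort$ue_group
  if ("adherent" %in% names(cohort)) dat$adherent <- cohort$adherent
  dat[is.finite(dat$y), ]
}

# Fit on a prebuilt subject table; shared by the exported interface and the
# sweep/sensitivity hot paths.
fit_on_subject_data <- function(dat, adjusted, covs) {
  check_arm_support(dat)
  rhs <- paste(c("arm", if (adjusted) covs), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("fit_diet_effect: design is rank deficient; collinear columns: ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  V <- stats::vcov(fit)
  est <- -co[["armhigh"]]            # low is the reference level
  se <- sqrt(V["armhigh", "armhigh"])
  df <- fit$df.residual
  list(estimate = est, se = se, df = df,
       p_value = 2 * stats::pt(-abs(est / se), df),
       n_used = nrow(dat), model = fit)
}

covariate_terms <- function(covariates) {
  vapply(covariates, function(v) {
    if (v == "insulin30") "log(insulin30)" else v
  }, character(1))
}

#' Estimate the low- vs high-carbohydrate diet effect on TEE change
#'
#' Fits normalized TEE change at the two test-phase timepoints on diet arm
#' (all three arms enter the model; the reported contrast is low minus high),
#' a timepoint term, and optionally the baseline covariate set (sex, age,
#' weight, height, run-in weight loss, baseline TEE, log insulin-30,
#' enrollment cohort). Analysis is intention-to-treat: participants are
#' analyzed as randomized regardless of adherence.
#'
#' With balanced timepoints the compound-symmetry repeated-measures model and
#' ordinary least squares on subject means give the identical contrast and
#' standard error; `method = "subject_mean"` (default) uses the latter,
#' `method = "gls"` fits the long-format generalized-least-squares model via
#' \pkg{nlme} as an independent route.
#'
#' @param cohort Cohort tibble (any subset with both extreme arms present).
#' @param adjusted Logical: include the baseline covariate set?
#' @param config A [scenario_config()].
#' @param method `"subject_mean"` or `"gls"`.
#' @return A `diet_effect` object: the low-vs-high estimate (kcal/d), its SE,
#'   two-sided p from the t distribution with residual degrees of freedom,
#'   the number of participants used, and the covariate list.
#' @examples
#' cohort <- sample_cohort(scenario_config(), seed = 1)
#' fit_diet_effect(cohort, adjusted = TRUE, config = scenario_config())
#' @export
fit_diet_effect <- function(cohort, adjusted = TRUE, config = scenario_config(),
                            method = c("subject_mean", "gls")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "scenario_config"))
  check_arm_support(cohort)

  covs <- covariate_terms(config$analysis$covariates)

  if (method == "subject_mean") {
    res <- fit_on_subject_data(effect_subject_data(cohort, config), adjusted, covs)
    return(structure(
      c(res, list(adjusted = adjusted,
                  covariates = if (adjusted) unname(covs) else character(0),
                  method = method)),
      class = "diet_effect"
    ))
  } else {
    long <- effect_long_data(cohort, config)
    if (!requireNamespace("nlme", quietly = TRUE)) {
      stop("method = 'gls' requires the nlme package", call. = FALSE)
    }
    rhs <- paste(c("arm", "timepoint", if (adjusted) covs), collapse = " + ")
    fit <- nlme::gls(stats::as.formula(paste("y ~", rhs)), data = long,
                     correlation = nlme::corCompSymm(form = ~ 1 | id),
                     method = "REML")
    co <- stats::coef(fit)
    V <- stats::vcov(fit)
    est <- -co[["armhigh"]]
    se <- sqrt(V["armhigh", "armhigh"])
    n_used <- length(unique(long$id))
    df <- n_used - length(co) + 1      # between-subject residual df
  }
  p <- 2 * stats::pt(-abs(est / se), df)
  structure(
    list(estimate = est, se = se, p_value = p, df = df, n_used = n_used,
         adjusted = adjusted,
         covariates = if (adjusted) unname(covs) else character(0),
         method = method, model = fit),
    class = "diet_effect"
  )
}

check_arm_support <- function(cohort, min_per_arm = 3) {
  counts <- table(factor(cohort$arm, levels = arm_levels))
  if (counts[["low"]] < min_per_arm || counts[["high"]] < min_per_arm) {
    stop(sprintf(paste0("fit_diet_effect: need >= %d participants in each of ",
                        "the low and high arms (have %d and %d)"),
                 min_per_arm, counts[["low"]], counts[["high"]]),
         call. = FALSE)
  }
  invisible(counts)
}

#' @export
print.diet_effect <- function(x, ...) {
  cat(sprintf("Low- vs high-carbohydrate TEE effect (%s): %.1f kcal/d (SE %.1f), p = %.3g, n = %d\n",
              if (x$adjusted) "adjusted" else "unadjusted",
              x$estimate, x$se, x$p_value, x$n_used))
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a diet-effect fit
#'
#' @param x A `diet_effect` object.
#' @param ... Unused.
#' @return One-row tibble with term, estimate, SE, p and metadata.
#' @importFrom generics tidy
#' @export
#' @method tidy diet_effect
tidy.diet_effect <- function(x, ...) {
  tibble::tibble(
    term = "arm (low - high)",
    estimate = x$estimate,
    std.error = x$se,
    p.value = x$p_value,
    df = x$df
  )
}

#' Model-level summary of a diet-effect fit
#'
#' @param x A `diet_effect` object.
#' @param ... Unused.
#' @return One-row tibble with fit metadata.
#' @importFrom generics glance
#' @export
#' @method glance diet_effect
glance.diet_effect <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used,
    adjusted = x$adjusted,
    method = x$method,
    n_covariates = length(x$covariates)
  )
}

#' @export
generics::tidy

#' @export
generics::glance
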