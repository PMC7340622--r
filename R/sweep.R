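# The sequential exclusion sweep: drop the highest-UE quantile bins one at a
# time, refit the diet effect with and without covariate adjustment, and
# express each step's estimate as attenuation relative to the full cohort.
# Successive steps reuse most of the same participants, so the points of the
# resulting curve are not independent: the package deliberately offers no
# trend-line fit across sweep steps, only the curve itself.

#' Sequential highest-UE exclusion sweep
#'
#' Quantile bins are computed once on the full cohort and frozen. At step
#' `k` the participants in bins `1..k` (the k highest-UE bins) are dropped
#' and both estimators are refit on the remainder; attenuation is
#' `1 - estimate_k / estimate_0`, within estimator. Steps where a model can
#' no longer be fit are recorded as `NA` with the reason, and the sweep
#' continues.
#'
#' @param cohort Cohort tibble with `ue_bin` assigned (see
#'   [add_unaccounted_energy()]).
#' @param config A [scenario_config()].
#' @param max_excluded Deepest step; defaults to `config$analysis$max_excluded`
#'   (18 of 36 bins, i.e. half the cohort).
#' @param per_protocol If `TRUE`, restrict to adherent participants before
#'   sweeping (the default is intention-to-treat).
#' @return A `ue_sweep` tibble: one row per step with `n_retained`,
#'   estimate/SE/p for both estimators, both attenuations, and a reason
#'   column for undefined steps.
#' @examples
#' cfg <- scenario_config()
#' sweep <- sample_cohort(cfg, seed = 1) |>
#'   add_unaccounted_energy(cfg) |>
#'   sequential_exclusion(cfg)
#' @export
sequential_exclusion <- function(cohort, config, max_excluded = NULL,
                                 per_protocol = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (!"ue_bin" %in% names(cohort)) {
    stop("sequential_exclusion: cohort lacks 'ue_bin'; ",
         "run add_unaccounted_energy() first", call. = FALSE)
  }
  if (per_protocol) cohort <- dplyr::filter(cohort, .data$adherent)
  max_excluded <- max_excluded %||% config$analysis$max_excluded

  sdat <- effect_subject_data(cohort, config)
  covs <- covariate_terms(config$analysis$covariates)
  fit_one <- function(dat, adjusted) {
    tryCatch({
      f <- fit_on_subject_data(dat, adjusted = adjusted, covs = covs)
      list(est = f$estimate, se = f$se, p = f$p_value, reason = NA_character_)
    }, error = function(e) {
      list(est = NA_real_, se = NA_real_, p = NA_real_,
           reason = conditionMessage(e))
    })
  }

  rows <- purrr::map(0:max_excluded, function(k) {
    retained <- sdat[sdat$ue_bin > k, ]
    fu <- fit_one(retained, adjusted = FALSE)
    fa <- fit_one(retained, adjusted = TRUE)
    tibble::tibble(
      k_excluded = k,
      n_retained = nrow(retained),
      estimate_unadjusted = fu$est, se_unadjusted = fu$se, p_unadjusted = fu$p,
      estimate_adjusted = fa$est, se_adjusted = fa$se, p_adjusted = fa$p,
      reason = dplyr::coalesce(fu$reason, fa$reason)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$attenuation_unadjusted <- 1 - out$estimate_unadjusted / out$estimate_unadjusted[1]
  out$attenuation_adjusted <- 1 - out$estimate_adjusted / out$estimate_adjusted[1]
  structure(out, class = c("ue_sweep", class(out)),
            config = config, per_protocol = per_protocol)
}

#' @export
print.ue_sweep <- function(x, ...) {
  k <- max(x$k_excluded)
  cat(sprintf("<ue_sweep> %d steps, n %d -> %d\n", k,
              x$n_retained[1], x$n_retained[nrow(x)]))
  cat(sprintf("  attenuation at k = %d: unadjusted %.2f, adjusted %.2f\n",
              k, x$attenuation_unadjusted[nrow(x)],
              x$attenuation_adjusted[nrow(x)]))
  NextMethod()
}

#' Compare the diet effect between the low-UE and high-UE halves
#'
#' Fits the adjusted diet effect separately within each UE group and tests
#' the UE-group-by-diet interaction (does the low-vs-high-carbohydrate
#' contrast differ between the halves?) in a joint model restricted to the
#' two extreme arms.
#'
#' @param cohort Cohort with `ue_group` assigned.
#' @param config A [scenario_config()].
#' @return A list with the two `diet_effect` fits (`low_ue`, `high_ue`), the
#'   interaction estimate (difference of contrasts, kcal/d), its SE, and the
#'   two-sided interaction p-value.
#' @export
compare_extreme_groups <- function(cohort, config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  if (!"ue_group" %in% names(cohort)) {
    stop("compare_extreme_groups: cohort lacks 'ue_group'; ",
         "run add_unaccounted_energy() first", call. = FALSE)
  }
  if (dplyr::n_distinct(cohort$ue_group) < 2) {
    stop("compare_extreme_groups: both UE groups must be present", call. = FALSE)
  }
  fits <- lapply(c(low = "low", high = "high"), function(g) {
    fit_diet_effect(dplyr::filter(cohort, .data$ue_group == g),
                    adjusted = TRUE, config = config)
  })

  covs <- covariate_terms(config$analysis$covariates)
  dat <- effect_subject_data(cohort, config)
  dat <- dat[dat$arm %in% c("low", "high"), ]
  dat$arm <- droplevels(dat$arm)
  rhs <- paste(c("arm * ue_group", covs), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
  co <- summary(fit)$coefficients
  term <- "armhigh:ue_grouphigh"
  if (!term %in% rownames(co)) {
    stop("compare_extreme_groups: interaction term inestimable", call. = FALSE)
  }
  list(
    low_ue = fits$low,
    high_ue = fits$high,
    interaction_estimate = -co[term, "Estimate"],
    interaction_se = co[term, "Std. Error"],
    p_interaction = co[term, "Pr(>|t|)"]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
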