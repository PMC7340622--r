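# ggplot2 views of the result objects. The sweep points share participants
# across steps, so the plots draw the observed curve only -- deliberately no
# regression or smoothing layer across sweep steps.

#' Plot a sequential-exclusion sweep
#'
#' Draws the estimate (or attenuation) curve against the number of excluded
#' quantile bins for both estimators, highest-UE exclusions accumulating
#' from right to left. Points are connected but never smoothed or fitted:
#' successive steps are not independent.
#'
#' @param object A `ue_sweep` from [sequential_exclusion()].
#' @param what `"estimate"` (with +/- 1 SE ribbons) or `"attenuation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ue_sweep <- function(object, what = c("estimate", "attenuation"), ...) {
  what <- match.arg(what)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::starts_with(c("estimate_", "attenuation_", "se_")),
    names_to = c(".value", "estimator"),
    names_pattern = "(estimate|attenuation|se)_(.*)"
  )
  long$n_retained_lab <- long$n_retained
  if (what == "estimate") {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$n_retained, y = .data$estimate, colour = .data$estimator)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$se,
                                        ymax = .data$estimate + .data$se,
                                        fill = .data$estimator),
                           alpha = 0.15, colour = NA) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "participants retained (exclusions accumulate right to left)",
                    y = "low - high TEE effect (kcal/d)")
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$n_retained, y = .data$attenuation, colour = .data$estimator)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "participants retained (exclusions accumulate right to left)",
                    y = "attenuation (1 - estimate / full-cohort estimate)")
  }
  p + ggplot2::scale_x_reverse() + ggplot2::theme_minimal()
}

#' Plot a non-adherence sensitivity sweep
#'
#' @param object An `rq_sensitivity` from [nonadherence_sweep()].
#' @param ... Unused.
#' @return A ggplot object: mean estimate against non-adherence fraction for
#'   the apparent and conservative estimators.
#' @export
autoplot.rq_sensitivity <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$fraction, y = .data$mean_estimate, colour = .data$estimator)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "non-adherence fraction",
                  y = "mean low - high TEE effect (kcal/d)") +
    ggplot2::theme_minimal()
}

#' Plot a tail-depletion trajectory
#'
#' Mean signed latent TEE error among retained participants as exclusions
#' deepen, overall and for the two extreme arms.
#'
#' @param object A `tail_depletion` from [tail_depletion_diagnostic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tail_depletion <- function(object, ...) {
  if (is.null(object$trajectory)) {
    stop("autoplot.tail_depletion: no trajectory (cohort had no ue_bin)",
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    object$trajectory,
    cols = c("mean_err_retained", "mean_err_low_arm", "mean_err_high_arm"),
    names_to = "series", values_to = "mean_err"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k_excluded, y = .data$mean_err,
                                     colour = .data$series)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "quantile bins excluded (highest UE first)",
                  y = "mean signed TEE error among retained (kcal/d)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
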