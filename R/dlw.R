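# Doubly-labeled-water energetics. DLW yields CO2 production; converting it
# to energy expenditure requires an assumed respiratory quotient (RQ),
# normally the food quotient (FQ) of the prescribed diet. If the consumed
# diet differs, the assumed RQ is wrong and measured TEE is biased by a
# closed-form ratio of Weir factors.

#' Energy expenditure from CO2 production (abbreviated Weir equation)
#'
#' `EE = VCO2 * (weir_o2 / rq + weir_co2)`, with the urinary-nitrogen term
#' folded into the fuel-RQ constants.
#'
#' @param vco2 CO2 production, litres/day (> 0).
#' @param rq Respiratory quotient, in \[0.6, 1.1\].
#' @param weir_o2,weir_co2 Weir coefficients, kcal per litre of O2 and CO2.
#' @return Energy expenditure, kcal/day.
#' @examples
#' weir_energy_expenditure(500, 0.85)  # 2871.2 kcal/d
#' @export
weir_energy_expenditure <- function(vco2, rq, weir_o2 = 3.941, weir_co2 = 1.106) {
  if (any(vco2 <= 0)) stop("weir_energy_expenditure: vco2 must be > 0", call. = FALSE)
  check_rq(rq)
  vco2 * (weir_o2 / rq + weir_co2)
}

check_rq <- function(rq) {
  if (any(!is.finite(rq)) || any(rq < 0.6) || any(rq > 1.1)) {
    stop("respiratory quotient outside the physiological range [0.6, 1.1]",
         call. = FALSE)
  }
  invisible(rq)
}

#' Food quotient of a diet
#'
#' The energy-fraction-weighted mean of the fuel RQs: the RQ a fully adherent
#' eater of this diet would show at energy balance, and hence the RQ the DLW
#' calculation assumes.
#'
#' @param diet A [diet_composition()] (or any vector with carb/fat/protein
#'   fractions summing to 1).
#' @param fuel_rq Named fuel RQs for carb, fat, protein.
#' @return Dimensionless food quotient.
#' @examples
#' food_quotient(diet_composition(0.20, 0.60, 0.20))  # 0.793
#' @export
food_quotient <- function(diet, fuel_rq = c(carb = 1.000, fat = 0.710, protein = 0.835)) {
  if (!inherits(diet, "diet_composition")) {
    diet <- do.call(diet_composition, as.list(unname(diet)[1:3]))
  }
  sum(unclass(diet) * fuel_rq[c("carb", "fat", "protein")])
}

#' RQ-assumption bias ratio for DLW expenditure
#'
#' When DLW-measured CO2 production is converted to energy expenditure with
#' an assumed RQ that differs from the true one, apparent TEE equals true TEE
#' multiplied by
#' `(weir_o2/rq_assumed + weir_co2) / (weir_o2/rq_true + weir_co2)`.
#' Assuming too low an RQ (e.g. prescribing a low-carbohydrate diet to
#' someone secretly eating more carbohydrate) overstates TEE.
#'
#' @param rq_assumed RQ used in the DLW calculation (prescribed diet's FQ).
#' @param rq_true RQ actually realized (consumed diet's FQ).
#' @inheritParams weir_energy_expenditure
#' @return Multiplicative bias: apparent TEE / true TEE.
#' @examples
#' rq_bias_ratio(0.80, 0.85)  # 1.0505: TEE overstated by ~5%
#' @export
rq_bias_ratio <- function(rq_assumed, rq_true, weir_o2 = 3.941, weir_co2 = 1.106) {
  check_rq(rq_assumed); check_rq(rq_true)
  if (weir_o2 <= 0 || weir_co2 <= 0) {
    stop("rq_bias_ratio: Weir coefficients must be > 0", call. = FALSE)
  }
  (weir_o2 / rq_assumed + weir_co2) / (weir_o2 / rq_true + weir_co2)
}
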