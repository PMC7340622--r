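# Scenario configuration: every tunable of the generator and the analysis
# lives here, so a run is fully described by (config, seed).

#' Diet composition as energy fractions
#'
#' @param carb,fat,protein Fractions of total energy from each macronutrient.
#'   Must each lie in \[0, 1\] and sum to 1 (within 1e-9).
#' @return A named numeric vector of class `diet_composition`.
#' @examples
#' diet_composition(0.20, 0.60, 0.20)
#' @export
diet_composition <- function(carb, fat, protein) {
  x <- c(carb = carb, fat = fat, protein = protein)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("diet_composition: fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("diet_composition: fractions sum to %.12f, not 1", sum(x)),
         call. = FALSE)
  }
  structure(x, class = c("diet_composition", "numeric"))
}

default_scenario_list <- function() {
  list(
    n_participants = 145L,
    arm_fractions  = c(low = 1 / 3, mod = 1 / 3, high = 1 / 3),
    diets = list(
      low  = diet_composition(0.20, 0.60, 0.20),
      mod  = diet_composition(0.40, 0.40, 0.20),
      high = diet_composition(0.60, 0.20, 0.20)
    ),
    # kcal/d of extra expenditure per 10 percentage-point decrease in dietary
    # carbohydrate, anchored at the 40% reference diet and scaled to an
    # 82-kg post-weight-loss body so the per-kg effect is homogeneous.
    cim_slope = 62.5,
    covariates = list(
      female_p        = 0.69,
      age_meanlog     = log(35.7),
      age_sdlog       = 0.559,
      weight_mean     = c(female = 87, male = 101),    # kg
      weight_sd       = c(female = 17, male = 19),
      height_mean     = c(female = 163.5, male = 178), # cm
      height_sd       = c(female = 7, male = 7),
      insulin30_meanlog = log(113.5),                  # uIU/ml
      insulin30_sdlog   = 0.5838,
      n_cohorts       = 3L,
      runin_mean      = 10.5,                          # % weight lost in run-in
      runin_sd        = 1.6,
      race_p          = c(white = 0.786, black = 0.103,
                          asian = 0.034, other = 0.077),
      hispanic_p      = 0.145,
      body_fat_mean   = 40.7,                          # % by DXA
      body_fat_sd     = 6.4
    ),
    baseline_tee = list(
      intercept = 883,   # kcal/d
      male      = 400,   # kcal/d added for males
      per_kg    = 15,    # kcal/d per kg body weight
      per_cm    = 5,     # kcal/d per cm height
      per_year  = -5,    # kcal/d per year of age
      resid_sd  = 560,   # biological residual, kcal/d
      reference = 3008   # cohort reference TEE used to scale relative errors
    ),
    test_phase = list(
      drift_per_kcal   = 0.4,  # maintenance-phase TEE drift per kcal/d of
                               # baseline deviation from the cohort reference
      subject_sd       = 100,  # subject-level random intercept, kcal/d
      timepoint_effect = -30,  # kcal/d shift at the second test timepoint
      maintenance_sd   = 0     # kcal/d noise around exact weight maintenance
    ),
    errors = list(
      tee_sd   = 150,    # DLW error at the reference TEE (CV ~5%); scales
                         # with the TEE actually being measured
      ei_sd    = 120,    # random error of intake records, kcal/d (absolute)
      dfm_sd   = 0.010,  # fat-mass-change rate error, kg/d
      underreport_kcal    = -300, # systematic recorded-minus-consumed intake
                                  # at the reference TEE, kcal/d
      underreport_scaling = 2.5,  # exponent on relative TEE for under-recording
      intake_lag = 1     # fraction of the diet-induced TEE change absent from
                         # intake records (provisions anchored to prescription)
    ),
    nonadherence = list(
      fraction = 0,      # proportion flagged non-adherent per arm
      drift    = 0.5     # proportion of the gap to 40% carbohydrate closed
    ),
    energetics = list(
      rho_fm  = 9441,    # energy density of fat-mass change, kcal/kg
      weir_o2 = 3.941,   # kcal per litre O2
      weir_co2 = 1.106,  # kcal per litre CO2
      fuel_rq = c(carb = 1.000, fat = 0.710, protein = 0.835)
    ),
    analysis = list(
      reference_weight = 82,   # kg; TEE change normalized to this weight
      n_quantile_bins  = 36L,
      max_excluded     = 18L,  # bins dropped at the deepest sweep step
      covariates = c("sex", "age", "weight", "height", "runin_loss",
                     "tee_base_meas", "insulin30", "cohort")
    ),
    missingness = 0
  )
}

#' Build a scenario configuration
#'
#' Returns the full parameter set driving cohort simulation and analysis.
#' The defaults encode a 145-participant, three-arm (20/40/60% carbohydrate)
#' feeding trial during weight-loss maintenance: baseline total energy
#' expenditure (TEE) averaging 3008 (SD 718) kcal/d, a programmed low- vs
#' high-carbohydrate effect of 250 kcal/d (normalized to 82 kg), and a
#' measurement-error structure in which Unaccounted Energy is linked both to
#' body size and to the doubly-labeled-water error shared with the outcome.
#'
#' @param ... Named overrides. Top-level scalars are replaced
#'   (`n_participants = 72`); nested groups are merged by name
#'   (`errors = list(tee_sd = 0)` changes only that field). Unknown names,
#'   at either level, are an error.
#' @return A validated list of class `scenario_config`.
#' @examples
#' cfg <- scenario_config()
#' noise_free <- scenario_config(
#'   errors = list(tee_sd = 0, ei_sd = 0, dfm_sd = 0,
#'                 underreport_kcal = 0, intake_lag = 0)
#' )
#' @export
scenario_config <- function(...) {
  cfg <- default_scenario_list()
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("scenario_config: all overrides must be named", call. = FALSE)
  }
  cfg <- merge_config(cfg, overrides, path = "")
  cfg <- validate_scenario(cfg)
  cfg
}

merge_config <- function(base, overrides, path) {
  for (nm in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base)) {
      stop(sprintf("scenario_config: unknown field '%s'", full), call. = FALSE)
    }
    val <- overrides[[nm]]
    if (is.list(base[[nm]]) && !inherits(base[[nm]], "diet_composition") &&
        is.list(val) && !inherits(val, "diet_composition")) {
      base[[nm]] <- merge_config(base[[nm]], val, full)
    } else {
      base[[nm]] <- val
    }
  }
  base
}

check_that <- function(ok, what) {
  if (!isTRUE(ok)) stop(sprintf("invalid scenario: %s", what), call. = FALSE)
}

#' @keywords internal
validate_scenario <- function(cfg) {
  check_that(is.numeric(cfg$n_participants) && cfg$n_participants >= 6,
             "n_participants must be a count >= 6")
  cfg$n_participants <- as.integer(cfg$n_participants)
  af <- cfg$arm_fractions
  check_that(length(af) == 3 && all(af > 0) && abs(sum(af) - 1) < 1e-9,
             "arm_fractions must be 3 positive proportions summing to 1")
  check_that(identical(sort(names(af)), sort(c("low", "mod", "high"))),
             "arm_fractions must be named low, mod, high")
  check_that(identical(sort(names(cfg$diets)), sort(c("low", "mod", "high"))),
             "diets must be named low, mod, high")
  for (nm in names(cfg$diets)) {
    d <- cfg$diets[[nm]]
    if (!inherits(d, "diet_composition")) {
      d <- do.call(diet_composition, as.list(unname(d)[1:3]))
      cfg$diets[[nm]] <- d
    }
  }
  check_that(is.numeric(cfg$cim_slope) && length(cfg$cim_slope) == 1,
             "cim_slope must be a single number (kcal/d per 10% carbohydrate)")
  cv <- cfg$covariates
  check_that(cv$female_p >= 0 && cv$female_p <= 1, "covariates$female_p in [0,1]")
  check_that(cv$hispanic_p >= 0 && cv$hispanic_p <= 1, "covariates$hispanic_p in [0,1]")
  check_that(abs(sum(cv$race_p) - 1) < 1e-9 && all(cv$race_p >= 0),
             "covariates$race_p must be proportions summing to 1")
  check_that(cv$n_cohorts >= 1, "covariates$n_cohorts must be >= 1")
  for (f in c("age_sdlog", "insulin30_sdlog", "runin_sd", "body_fat_sd")) {
    check_that(cv[[f]] >= 0, sprintf("covariates$%s must be >= 0", f))
  }
  check_that(all(cv$weight_sd >= 0) && all(cv$height_sd >= 0),
             "covariate SDs must be >= 0")
  check_that(cfg$baseline_tee$resid_sd >= 0, "baseline_tee$resid_sd must be >= 0")
  check_that(cfg$baseline_tee$reference > 0, "baseline_tee$reference must be > 0")
  check_that(cfg$test_phase$subject_sd >= 0, "test_phase$subject_sd must be >= 0")
  check_that(cfg$test_phase$maintenance_sd >= 0, "test_phase$maintenance_sd must be >= 0")
  er <- cfg$errors
  for (f in c("tee_sd", "ei_sd", "dfm_sd")) {
    check_that(er[[f]] >= 0, sprintf("errors$%s must be >= 0", f))
  }
  check_that(er$underreport_scaling >= 0, "errors$underreport_scaling must be >= 0")
  na <- cfg$nonadherence
  check_that(na$fraction >= 0 && na$fraction <= 1, "nonadherence$fraction in [0,1]")
  check_that(na$drift >= 0 && na$drift <= 1, "nonadherence$drift in [0,1]")
  en <- cfg$energetics
  check_that(en$rho_fm > 0, "energetics$rho_fm must be > 0")
  check_that(en$weir_o2 > 0 && en$weir_co2 > 0, "Weir coefficients must be > 0")
  check_that(all(en$fuel_rq >= 0.6) && all(en$fuel_rq <= 1.1),
             "energetics$fuel_rq values must lie in [0.6, 1.1]")
  an <- cfg$analysis
  check_that(an$reference_weight > 0, "analysis$reference_weight must be > 0")
  check_that(an$n_quantile_bins >= 2, "analysis$n_quantile_bins must be >= 2")
  cfg$analysis$n_quantile_bins <- as.integer(an$n_quantile_bins)
  check_that(an$max_excluded >= 1 && an$max_excluded < an$n_quantile_bins,
             "analysis$max_excluded must lie in [1, n_quantile_bins)")
  cfg$analysis$max_excluded <- as.integer(an$max_excluded)
  check_that(cfg$missingness >= 0 && cfg$missingness < 1, "missingness in [0,1)")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  n = %d, arms low/mod/high = %.0f/%.0f/%.0f%% carbohydrate\n",
              x$n_participants, 100 * x$diets$low["carb"],
              100 * x$diets$mod["carb"], 100 * x$diets$high["carb"]))
  cat(sprintf("  programmed low-vs-high effect: %.1f kcal/d (slope %.1f per 10%%)\n",
              4 * x$cim_slope, x$cim_slope))
  cat(sprintf("  non-adherence: fraction %.2f, drift %.2f\n",
              x$nonadherence$fraction, x$nonadherence$drift))
  cat(sprintf("  error SDs: TEE %.0f, intake %.0f kcal/d, fat-mass %.3f kg/d\n",
              x$errors$tee_sd, x$errors$ei_sd, x$errors$dfm_sd))
  invisible(x)
}

#' Read / write a scenario configuration file
#'
#' Scenario files are YAML or JSON mirrors of [scenario_config()]'s nested
#' structure. Unknown keys are rejected so typos cannot silently fall back to
#' defaults. Omitted keys take their default values.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return For `read_scenario()`, a validated `scenario_config`.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("read_scenario: unsupported extension '", ext, "'", call. = FALSE)
  )
  # yaml/json read named vectors back as lists; restore where needed
  raw <- rapply(raw, function(x) x, how = "replace")
  raw <- normalize_scenario_io(raw)
  do.call(scenario_config, raw)
}

normalize_scenario_io <- function(raw) {
  unlist_vec <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, TRUE))) {
      unlist(x)
    } else x
  }
  for (nm in intersect(names(raw), c("arm_fractions"))) raw[[nm]] <- unlist_vec(raw[[nm]])
  if (!is.null(raw$diets)) {
    raw$diets <- lapply(raw$diets, function(d) {
      d <- unlist_vec(d)
      do.call(diet_composition, as.list(unname(d)[1:3]))
    })
  }
  for (grp in c("covariates", "baseline_tee", "test_phase", "errors",
                "nonadherence", "energetics", "analysis")) {
    if (!is.null(raw[[grp]])) raw[[grp]] <- lapply(raw[[grp]], unlist_vec)
  }
  raw
}

#' @rdname read_scenario
#' @param config A `scenario_config`.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  # named vectors become maps (yaml would silently drop the names otherwise)
  to_plain <- function(x) {
    if (is.list(x)) lapply(x, to_plain)
    else if (is.atomic(x) && !is.null(names(x))) as.list(unclass(x))
    else unclass(x)
  }
  plain <- to_plain(unclass(config))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "yaml" = , "yml" = yaml::write_yaml(plain, path, precision = 15),
    "json" = jsonlite::write_json(plain, path, auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE),
    stop("write_scenario: unsupported extension '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Deterministic child seed for a pipeline stage
#'
#' All randomness descends from one master seed; each stage draws from its own
#' deterministic child so stages can be re-run in isolation.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name.
#' @return An integer seed in \[0, 2^31).
#' @export
child_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, ue = 2L, sweep = 3L, table1 = 4L,
               sensitivity = 5L, replicates = 6L, extra = 7L)
  off <- offsets[[match.arg(stage, names(offsets))]]
  (as.integer(seed) %% 1000003L) * 2011L + off * 7919L
}
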