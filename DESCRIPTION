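Package: uebias
Title: Post-Randomization Exclusion Bias in Controlled Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying the confounding bias
    introduced when participants of a randomized feeding trial are excluded
    post hoc on "Unaccounted Energy" (UE), the absolute gap between measured
    energy intake and expenditure corrected for body-fat change. Provides a
    synthetic cohort generator calibrated to a three-arm carbohydrate feeding
    trial (20/40/60% of energy), closed-form doubly-labeled-water energetics
    (Weir equation, food quotients, respiratory-quotient bias ratios), the UE
    statistic with median dichotomization and quantile binning, unadjusted and
    covariate-adjusted diet-effect estimation, sequential quantile-exclusion
    sweeps with attenuation curves, baseline-imbalance tables, and a
    sensitivity suite covering non-adherence, symmetric-tail exclusion, and
    tail-depletion diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
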