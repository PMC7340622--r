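# Baseline-imbalance machinery: the tests used to compare participant
# characteristics between the low- and high-UE halves (Pearson chi-squared
# without continuity correction, pooled-variance two-sample t, Wilcoxon rank
# sum), plus assembly of the full comparison table.

#' Pearson chi-squared test of independence (no continuity correction)
#'
#' @param counts An r x c matrix of non-negative counts (at least 2 x 2).
#' @return Tibble with statistic, df and upper-tail p-value.
#' @examples
#' chi_squared_test(rbind(c(60, 13), c(40, 32)))  # p = 0.0005
#' @export
chi_squared_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("chi_squared_test: need at least a 2x2 table", call. = FALSE)
  }
  if (any(counts < 0)) stop("chi_squared_test: counts must be >= 0", call. = FALSE)
  zr <- which(rowSums(counts) == 0); zc <- which(colSums(counts) == 0)
  if (length(zr) || length(zc)) {
    stop(sprintf("chi_squared_test: zero marginal in row(s) [%s], column(s) [%s]",
                 paste(zr, collapse = ","), paste(zc, collapse = ",")),
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Pooled-variance two-sample t test
#'
#' Student's equal-variance t from summary statistics (mean, SD, n per
#' group), or from raw samples via `pooled_t_test_raw()`; both routes agree
#' exactly. Degrees of freedom are `n1 + n2 - 2`; the p-value is two-sided.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Tibble with t, df and p.
#' @examples
#' pooled_t_test(87.1, 16.8, 73, 95.6, 18.9, 72)
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("pooled_t_test: need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("pooled_t_test: SDs must be >= 0", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    # zero pooled variance: identical constants give t = 0 / p = 1; any mean
    # difference is then infinitely many SEs away
    t <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
    p <- if (mean1 == mean2) 1 else 0
    return(tibble::tibble(statistic = t, df = df, p_value = p))
  }
  t <- (mean1 - mean2) / se
  tibble::tibble(statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df))
}

#' @rdname pooled_t_test
#' @param x,y Raw samples.
#' @export
pooled_t_test_raw <- function(x, y) {
  pooled_t_test(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y))
}

#' Wilcoxon rank-sum test
#'
#' Mid-ranks for ties; exact enumeration when the combined sample size is at
#' most 12 and there are no ties, otherwise the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Combined-size threshold for the exact test.
#' @return Tibble with the rank-sum statistic (Mann-Whitney U of `x`) and p.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) {
    stop("wilcoxon_rank_sum: both samples must be non-empty", call. = FALSE)
  }
  if (all(c(x, y) == c(x, y)[1])) {
    return(tibble::tibble(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= exact_max) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = unname(res$p.value))
}

table1_variables <- function() {
  tibble::tribble(
    ~variable,     ~kind,
    "race",        "categorical",
    "hispanic",    "categorical",
    "sex",         "categorical",
    "age",         "skewed",
    "weight",      "normal",
    "height",      "normal",
    "bmi",         "normal",
    "body_fat",    "normal",
    "insulin30",   "skewed",
    "tee_base_meas", "normal",
    "ei_meas",     "normal",
    "runin_loss",  "normal"
  )
}

#' Baseline-characteristics comparison table between UE groups
#'
#' One row per baseline variable, comparing the low- and high-UE halves:
#' categorical variables by Pearson chi-squared, roughly symmetric numeric
#' variables by the pooled t test, and skewed variables (age, insulin-30) by
#' the Wilcoxon rank-sum test. Percentages are shown to one decimal, p-values
#' to four.
#'
#' @param cohort Cohort with `ue_group` assigned.
#' @param variables Optional character subset of variables; unknown names are
#'   skipped with a warning.
#' @return A tibble with per-group summaries, the test used, its statistic
#'   and p-value.
#' @export
build_baseline_table <- function(cohort, variables = NULL) {
  if (!"ue_group" %in% names(cohort)) {
    stop("build_baseline_table: cohort lacks 'ue_group'; ",
         "run add_unaccounted_energy() first", call. = FALSE)
  }
  spec <- table1_variables()
  if (!is.null(variables)) {
    unknown <- setdiff(variables, spec$variable)
    if (length(unknown)) {
      warning("build_baseline_table: skipping unknown variable(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    spec <- spec[spec$variable %in% variables, ]
  }
  spec <- spec[spec$variable %in% names(cohort), ]
  g <- cohort$ue_group

  one_row <- function(variable, kind) {
    v <- cohort[[variable]]
    if (kind == "categorical") {
      tab <- table(factor(v), g)
      res <- chi_squared_test(as.matrix(tab))
      summarise_grp <- function(grp) {
        cnt <- table(factor(v)[g == grp])
        paste(sprintf("%s %d (%.1f%%)", names(cnt), as.integer(cnt),
                      100 * as.integer(cnt) / sum(cnt)), collapse = "; ")
      }
      tibble::tibble(variable = variable, test = "chi-squared",
                     low_ue = summarise_grp("low"), high_ue = summarise_grp("high"),
                     statistic = res$statistic, p_value = res$p_value)
    } else if (kind == "normal") {
      res <- pooled_t_test_raw(v[g == "low"], v[g == "high"])
      fmt <- function(grp) sprintf("%.1f (%.1f)", mean(v[g == grp]),
                                   stats::sd(v[g == grp]))
      tibble::tibble(variable = variable, test = "pooled t",
                     low_ue = fmt("low"), high_ue = fmt("high"),
                     statistic = res$statistic, p_value = res$p_value)
    } else {
      res <- wilcoxon_rank_sum(v[g == "low"], v[g == "high"])
      fmt <- function(grp) {
        q <- stats::quantile(v[g == grp], c(0.25, 0.5, 0.75))
        sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
      }
      tibble::tibble(variable = variable, test = "wilcoxon",
                     low_ue = fmt("low"), high_ue = fmt("high"),
                     statistic = res$statistic, p_value = res$p_value)
    }
  }
  out <- purrr::pmap(spec, function(variable, kind) one_row(variable, kind))
  dplyr::bind_rows(out)
}

#' Render a baseline table as aligned text
#'
#' @param table1 Output of [build_baseline_table()].
#' @return Character vector of formatted lines (invisibly printed).
#' @export
format_baseline_table <- function(table1) {
  lines <- sprintf("%-14s %-11s low: %-28s high: %-28s p = %.4f",
                   table1$variable, table1$test, table1$low_ue,
                   table1$high_ue, table1$p_value)
  lines
}
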