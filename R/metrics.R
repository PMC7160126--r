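# Refractive prediction-error summaries and formula comparison reports.

#' Summarize a series of refractive prediction errors
#'
#' Standard outcome statistics for a vector of per-eye prediction errors
#' (observed minus predicted spherical equivalent, D): mean error with
#' sample SD, median error, mean and median absolute error, interquartile
#' range, and the percentage of eyes within 0.50, 1.00 and 1.50 D.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the within-threshold comparisons are
#' inclusive; SDs are the n - 1 sample SD.
#'
#' @param pe Numeric vector of prediction errors (D), n >= 1, no missing
#'   values. `sd`, `sd_ae` and `iqr` are `NA` for a single observation.
#' @return An object of class `"error_summary"`: list with `n`, `me`,
#'   `sd`, `median_error`, `mae`, `sd_ae`, `median_ae`, `iqr`,
#'   `pct_within_05`, `pct_within_10`, `pct_within_15`.
#' @export
#' @examples
#' summarize_errors(c(-0.5, 0, 0.5, 1))
summarize_errors <- function(pe) {
  if (length(pe) == 0L) stop("empty prediction-error series", call. = FALSE)
  .check_num(pe, "pe")
  ae <- abs(pe)
  one <- length(pe) < 2L
  q <- unname(stats::quantile(pe, c(0.25, 0.75), type = 7))
  structure(list(
    n = length(pe),
    me = mean(pe),
    sd = if (one) NA_real_ else stats::sd(pe),
    median_error = unname(stats::median(pe)),
    mae = mean(ae),
    sd_ae = if (one) NA_real_ else stats::sd(ae),
    median_ae = unname(stats::median(ae)),
    iqr = if (one) NA_real_ else q[2L] - q[1L],
    pct_within_05 = 100 * mean(ae <= 0.5),
    pct_within_10 = 100 * mean(ae <= 1.0),
    pct_within_15 = 100 * mean(ae <= 1.5)),
    class = "error_summary")
}

#' @export
print.error_summary <- function(x, digits = 2, ...) {
  f <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = digits,
                                                  format = "f"))
  cat(sprintf("Prediction errors, n = %d eyes\n", x$n))
  cat(sprintf("  ME (D) +- SD     %s +- %s\n", f(x$me), f(x$sd)))
  cat(sprintf("  Median error (D) %s\n", f(x$median_error)))
  cat(sprintf("  MAE (D) +- SD    %s +- %s\n", f(x$mae), f(x$sd_ae)))
  cat(sprintf("  Median AE (D)    %s\n", f(x$median_ae)))
  cat(sprintf("  IQR (D)          %s\n", f(x$iqr)))
  cat(sprintf("  Within 0.5/1.0/1.5 D  %s%% / %s%% / %s%%\n",
              f(x$pct_within_05), f(x$pct_within_10), f(x$pct_within_15)))
  invisible(x)
}

#' @export
as.data.frame.error_summary <- function(x, ...) {
  data.frame(statistic = c("n", "me", "sd", "median_error", "mae", "sd_ae",
                           "median_ae", "iqr", "pct_within_05",
                           "pct_within_10", "pct_within_15"),
             value = unlist(x, use.names = FALSE))
}

#' Compare IOL formulas on one cohort
#'
#' Evaluates each requested formula on every eye of a cohort with
#' [predict_cohort()] and summarizes the resulting prediction errors with
#' [summarize_errors()], giving a report in the shape of the familiar
#' outcome tables (one column per formula, one row per statistic).
#'
#' @param cohort Cohort data frame with implanted powers and observed
#'   postoperative refractions.
#' @param formulas Character vector of formula identifiers.
#' @inheritParams predict_cohort
#' @return An object of class `"formula_comparison"`: a named list of
#'   [summarize_errors()] results, one per formula.
#'   `as.data.frame()` renders the statistic-by-formula table.
#' @export
#' @examples
#' cohort <- generate_cohort(training_cohort_params(seed = 3))
#' compare_formulas(cohort, c("haigis-l", "modified-haigis-l"))
compare_formulas <- function(cohort,
                             formulas = c("haigis-l", "modified-haigis-l"),
                             constants = zcb00_constants(), vd = 12,
                             keratometric_index = 1.3315,
                             model = pe_model()) {
  formulas <- vapply(formulas, match.arg, "", choices = FORMULA_IDS)
  if (nrow(cohort) == 0L)
    stop("empty cohort: nothing to evaluate", call. = FALSE)
  if (!"postop_se_d" %in% names(cohort) || anyNA(cohort$postop_se_d))
    stop("formula comparison needs an observed 'postop_se_d' for every case",
         call. = FALSE)
  out <- lapply(formulas, function(fm) {
    scored <- predict_cohort(cohort, fm, constants = constants, vd = vd,
                             keratometric_index = keratometric_index,
                             model = model)
    summarize_errors(scored$pe_d)
  })
  names(out) <- unname(formulas)
  structure(out, class = "formula_comparison")
}

#' @export
as.data.frame.formula_comparison <- function(x, ...) {
  cols <- lapply(unclass(x), function(s) unlist(s, use.names = FALSE))
  out <- data.frame(statistic = c("n", "me", "sd", "median_error", "mae",
                                  "sd_ae", "median_ae", "iqr",
                                  "pct_within_05", "pct_within_10",
                                  "pct_within_15"),
                    cols, check.names = FALSE)
  names(out) <- c("statistic", names(x))
  out
}

#' @export
print.formula_comparison <- function(x, digits = 2, ...) {
  tab <- as.data.frame(x)
  tab[-1] <- lapply(tab[-1], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}
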