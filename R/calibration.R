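# Calibration of the spherical-aberration correction: correlation
# screening of biometric predictors against Haigis-L prediction error,
# OLS of PE on SA8, and the user-facing sa_calibrate() fit.

.check_series_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("series must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("at least 3 paired observations are required", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("series must not contain missing values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate series: constant input has no defined correlation",
         call. = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two series, with the p-value from
#' the two-sided t test on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return A list with `r`, `p_value`, and `n`.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 2, 4, 4))  # r = 0.894
pearson_cor <- function(x, y) {
  .check_series_pair(x, y)
  ct <- stats::cor.test(x, y, alternative = "two.sided", method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Fit the prediction-error-on-spherical-aberration regression
#'
#' Ordinary least squares of the Haigis-L prediction error (D) on
#' anterior-corneal spherical aberration at the 8.0 mm zone (um), with
#' Pearson correlation diagnostics. This is the regression whose published
#' training-set coefficients are the [pe_model()] defaults.
#'
#' @param sa Spherical aberration values (um), non-constant, n >= 3.
#' @param pe Haigis-L prediction errors (D).
#' @return An object of class `"pe_regression"`: list with `slope`,
#'   `intercept`, `r`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
#' @examples
#' fit_pe_regression(c(1, 2, 3, 4), c(2, 2, 4, 4))  # slope 0.8, intercept 1
fit_pe_regression <- function(sa, pe) {
  .check_series_pair(sa, pe)
  if (stats::sd(sa) == 0)
    stop("degenerate predictor: spherical aberration is constant",
         call. = FALSE)
  fit <- stats::lm(pe ~ sa, data = data.frame(sa = sa, pe = pe))
  ct <- stats::cor.test(sa, pe)
  structure(list(slope = unname(stats::coef(fit)[["sa"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(sa), lm = fit),
            class = "pe_regression")
}

#' @export
print.pe_regression <- function(x, ...) {
  cat(sprintf("PE regression (n = %d):\n  PE = %.4f * SA8 %+.4f\n", x$n,
              x$slope, x$intercept))
  cat(sprintf("  Pearson r = %.3f, p = %.3g\n", x$r, x$p_value))
  invisible(x)
}

# short predictor names <-> cohort columns
.PREDICTOR_COLS <- c(AL = "axial_length_mm", ACD = "acd_mm",
                     r = "mean_corneal_radius_mm", Q6 = "q6", Q8 = "q8",
                     SA6 = "sa6_um", SA8 = "sa8_um",
                     ecc6 = "ecc6", ecc8 = "ecc8")

#' Screen biometric predictors against prediction error
#'
#' Pearson correlation of each available biometric predictor (axial
#' length, anterior chamber depth, corneal radius, Q-values, spherical
#' aberrations, eccentricities) with the per-eye prediction error, sorted
#' by decreasing absolute correlation. Constant predictors are flagged as
#' degenerate rather than aborting the screen.
#'
#' @param cohort Cohort data frame containing a prediction-error column
#'   (compute one with [predict_cohort()]).
#' @param pe_col Name of the prediction-error column (default `"pe_d"`).
#' @param predictors Character vector of predictor names among `"AL"`,
#'   `"ACD"`, `"r"`, `"Q6"`, `"Q8"`, `"SA6"`, `"SA8"`, `"ecc6"`, `"ecc8"`;
#'   defaults to those present in `cohort`.
#' @return A data frame with columns `predictor`, `r`, `p`, `n`,
#'   `degenerate`, ordered by `abs(r)` descending (degenerate rows last).
#' @export
correlate_predictors <- function(cohort, pe_col = "pe_d",
                                 predictors = NULL) {
  if (!pe_col %in% names(cohort))
    stop("cohort has no '", pe_col, "' column; run predict_cohort() first",
         call. = FALSE)
  pe <- cohort[[pe_col]]
  if (anyNA(pe))
    stop("prediction error must be present for every case", call. = FALSE)
  if (is.null(predictors))
    predictors <- names(.PREDICTOR_COLS)[.PREDICTOR_COLS %in% names(cohort)]
  unknown <- setdiff(predictors, names(.PREDICTOR_COLS))
  if (length(unknown))
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  absent <- predictors[!.PREDICTOR_COLS[predictors] %in% names(cohort)]
  if (length(absent))
    stop("predictor column(s) absent from cohort: ",
         paste(.PREDICTOR_COLS[absent], collapse = ", "), call. = FALSE)
  rows <- lapply(predictors, function(p) {
    x <- cohort[[.PREDICTOR_COLS[[p]]]]
    res <- tryCatch(pearson_cor(x, pe),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(predictor = p, r = NA_real_, p = NA_real_,
                 n = length(x), degenerate = TRUE)
    else
      data.frame(predictor = p, r = res$r, p = res$p_value,
                 n = res$n, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$degenerate, -abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the spherical-aberration correction on a cohort
#'
#' The central fitting function of the package. Evaluates the Haigis-L
#' formula on every eye of a training cohort (implanted power and observed
#' postoperative spherical equivalent required), regresses the resulting
#' prediction error on the 8.0 mm-zone spherical aberration by ordinary
#' least squares, and returns the fitted correction as a classed model
#' object whose [pe_model()] can drive the modified Haigis-L formula.
#'
#' The fit never touches held-out data: train/test splitting is the
#' caller's responsibility.
#'
#' @param cohort Training cohort data frame (see [read_cohort()] for the
#'   schema); must contain `sa8_um`, `implanted_power_d` and `postop_se_d`.
#' @param constants [iol_constants()] of the implanted lens.
#' @param vd Vertex distance (mm).
#' @return An object of class `"sa_fit"` with components `model`
#'   (the fitted [pe_model()]), `fit` (the [fit_pe_regression()]
#'   diagnostics), `data` (per-eye `sa8`, `pe`), `constants`, `vd`, `call`.
#'   Supported methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `fitted`, `plot`, `simulate`.
#' @seealso [predict.sa_fit()], [simulate.sa_fit()]
#' @export
#' @examples
#' cohort <- generate_cohort(training_cohort_params(seed = 7))
#' fit <- sa_calibrate(cohort)
#' coef(fit)
sa_calibrate <- function(cohort, constants = zcb00_constants(), vd = 12) {
  if (!"postop_se_d" %in% names(cohort) || anyNA(cohort$postop_se_d))
    stop("calibration needs an observed 'postop_se_d' for every case",
         call. = FALSE)
  scored <- predict_cohort(cohort, "haigis-l", constants = constants, vd = vd)
  fit <- fit_pe_regression(scored$sa8_um, scored$pe_d)
  structure(list(model = pe_model(fit$slope, fit$intercept),
                 fit = fit,
                 data = data.frame(sa8 = scored$sa8_um, pe = scored$pe_d),
                 constants = constants, vd = vd,
                 call = match.call()),
            class = "sa_fit")
}

#' @export
print.sa_fit <- function(x, ...) {
  cat("Spherical-aberration correction for the Haigis-L formula\n\n")
  print(x$fit)
  invisible(x)
}

#' @export
coef.sa_fit <- function(object, ...) {
  c(intercept = object$model$intercept, slope = object$model$slope)
}

#' @export
fitted.sa_fit <- function(object, ...) {
  pe_from_sa(object$data$sa8, object$model)
}

#' @export
residuals.sa_fit <- function(object, ...) {
  object$data$pe - fitted(object)
}

#' @export
summary.sa_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object$fit,
                 residual_sd = stats::sd(res),
                 residual_summary = summarize_errors(res),
                 n = object$fit$n),
            class = "summary.sa_fit")
}

#' @export
print.summary.sa_fit <- function(x, ...) {
  cat("Spherical-aberration correction for the Haigis-L formula\n\n")
  print(x$fit)
  cat(sprintf("  residual SD = %.3f D\n\n", x$residual_sd))
  cat("Residuals (modified-formula prediction error on the training set):\n")
  print(x$residual_summary)
  invisible(x)
}

#' Predict from a fitted spherical-aberration correction
#'
#' With a numeric `newdata`, returns the expected Haigis-L prediction
#' error (D) at those spherical-aberration values. With a cohort data
#' frame, evaluates the modified Haigis-L formula under the fitted
#' correction and returns the cohort with `predicted_se_d` / `pe_d`
#' columns (as [predict_cohort()]).
#'
#' @param object An `"sa_fit"` from [sa_calibrate()].
#' @param newdata Numeric vector of SA8 values (um), or a cohort data
#'   frame. Defaults to the training SA8 values.
#' @param ... Unused.
#' @return Numeric vector of expected prediction errors, or a scored
#'   cohort data frame.
#' @export
predict.sa_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$sa8
  if (is.data.frame(newdata))
    predict_cohort(newdata, "modified-haigis-l",
                   constants = object$constants, vd = object$vd,
                   model = object$model)
  else
    pe_from_sa(newdata, object$model)
}

#' Scatter plot of a fitted spherical-aberration correction
#'
#' Training-set prediction error against 8.0 mm-zone spherical aberration
#' with the fitted regression line.
#'
#' @param x An `"sa_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sa_fit <- function(x, ...) {
  graphics::plot(x$data$sa8, x$data$pe,
                 xlab = expression(SA[8*mm] ~ (mu * m)),
                 ylab = "Haigis-L prediction error (D)", ...)
  graphics::abline(x$model$intercept, x$model$slope, col = "red3", lwd = 2)
  graphics::mtext(sprintf("PE = %.3f SA8 %+.3f   (r = %.3f, n = %d)",
                          x$model$slope, x$model$intercept, x$fit$r,
                          x$fit$n), side = 3, line = 0.3, cex = 0.9)
  invisible(x)
}

#' Simulate cohorts from a fitted correction
#'
#' Generates synthetic cohorts whose prediction-error structure follows
#' the fitted regression (the fit's [pe_model()] becomes the generator's
#' truth), with residual spread equal to the fit's residual SD.
#'
#' @param object An `"sa_fit"`.
#' @param nsim Number of cohorts.
#' @param seed Root seed for the first cohort; cohort k uses `seed + k - 1`.
#' @param params Base [cohort_params()]; its `pe_model` and `residual_sd`
#'   are replaced by the fitted values.
#' @param ... Unused.
#' @return A list of `nsim` cohort data frames.
#' @export
simulate.sa_fit <- function(object, nsim = 1, seed = 1,
                            params = training_cohort_params(), ...) {
  res_sd <- stats::sd(residuals(object))
  lapply(seq_len(nsim), function(k) {
    p <- params
    p$pe_model <- object$model
    p$residual_sd <- res_sd
    p$seed <- as.integer(seed + k - 1L)
    generate_cohort(p)
  })
}
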