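# The three corneal-power conventions and per-eye prediction.
#
# Formula identifiers used throughout (and on the CLI):
#   "haigis"            keratometric power from the measured radius
#   "haigis-l"          regression-corrected effective corneal power
#   "modified-haigis-l" Haigis-L additionally corrected for anterior-corneal
#                       spherical aberration at the 8.0 mm zone

FORMULA_IDS <- c("haigis", "haigis-l", "modified-haigis-l")

#' Prediction-error regression model (spherical-aberration correction)
#'
#' The linear model relating the Haigis-L prediction error (D, spectacle
#' plane) to anterior-corneal spherical aberration at the 8.0 mm zone
#' (micrometers): `PE = slope * SA8 + intercept`. The default coefficients
#' are the published training-set regression (slope 0.583 D/um, intercept
#' -2.3488 D). Refit them on local data with [sa_calibrate()].
#'
#' @param slope Slope in D per micrometer of SA8.
#' @param intercept Intercept in D.
#' @return A list of class `"pe_model"`.
#' @export
#' @examples
#' pe_model()                      # published coefficients
#' pe_from_sa(3.69, pe_model())    # expected Haigis-L error at the mean SA8
pe_model <- function(slope = 0.583, intercept = -2.3488) {
  .check_num(slope, "slope"); .check_num(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept), class = "pe_model")
}

#' @export
print.pe_model <- function(x, ...) {
  cat(sprintf("PE model: PE = %g * SA8 %+g  (D; SA8 in um)\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Haigis-L effective corneal power
#'
#' Regression-corrected effective equivalent corneal power for
#' post-myopic-laser eyes: `-5.6125 * r + 82.2603 - 0.35` (D), where `r` is
#' the measured mean anterior corneal radius in mm. The regression corrects
#' the radius-measurement and keratometric-index biases that keratometry
#' acquires after myopic ablation; the additional -0.35 D offset removes
#' residual error attributed to lens-position estimation.
#'
#' @param r Mean anterior corneal radius (mm).
#' @return Effective corneal power (D).
#' @export
#' @examples
#' corneal_power_haigis_l(8.79)  # 32.57643
corneal_power_haigis_l <- function(r) {
  .check_num(r, "r", positive = TRUE)
  -5.6125 * r + 82.2603 - 0.35
}

#' Predicted Haigis-L prediction error from spherical aberration
#'
#' Evaluates the [pe_model()] line: the spectacle-plane prediction error
#' the Haigis-L formula is expected to make for an eye with the given
#' 8.0 mm-zone anterior-corneal spherical aberration.
#'
#' @param sa8 Spherical aberration at the 8.0 mm zone (um).
#' @param model A [pe_model()].
#' @return Expected prediction error (D, spectacle plane).
#' @export
pe_from_sa <- function(sa8, model = pe_model()) {
  .check_num(sa8, "sa8")
  stopifnot(inherits(model, "pe_model"))
  model$slope * sa8 + model$intercept
}

#' Spherical-aberration-corrected effective corneal power (Z')
#'
#' The modified Haigis-L corneal power: the Haigis-L power minus the
#' corneal-plane equivalent of the expected prediction error,
#' `Z' = (-5.6125 r + 82.2603 - 0.35) - REFc(slope * SA8 + intercept)`.
#' A positive expected error (hyperopic surprise) lowers Z', which raises
#' the computed IOL power and shifts the prediction toward the error.
#'
#' @inheritParams corneal_power_haigis_l
#' @inheritParams pe_from_sa
#' @param vd Vertex distance (mm) for the spectacle-to-corneal transform.
#' @return Corrected effective corneal power Z' (D).
#' @export
#' @examples
#' corneal_power_modified(8.79, 3.69)  # 32.77349
corneal_power_modified <- function(r, sa8, vd = 12, model = pe_model()) {
  corneal_power_haigis_l(r) -
    spectacle_to_corneal(pe_from_sa(sa8, model), vd)
}

# effective corneal power under a named formula; vectorized over biometry
.corneal_power_for <- function(formula_id, r, sa8 = NULL, vd = 12,
                               keratometric_index = 1.3315,
                               model = pe_model()) {
  formula_id <- match.arg(formula_id, FORMULA_IDS)
  switch(formula_id,
    "haigis"            = keratometric_power(r, keratometric_index),
    "haigis-l"          = corneal_power_haigis_l(r),
    "modified-haigis-l" = {
      if (is.null(sa8) || anyNA(sa8))
        stop("missing measurement: 'sa8_um' (spherical aberration at 8.0 mm) ",
             "is required by the modified-haigis-l formula", call. = FALSE)
      corneal_power_modified(r, sa8, vd = vd, model = model)
    })
}

#' Predict refraction for one eye under a chosen formula
#'
#' Convenience scalar interface: computes the effective lens position, the
#' formula's effective corneal power, the IOL power for a target
#' refraction, and (when an implanted power is given) the predicted
#' spectacle-plane spherical equivalent and prediction error.
#'
#' @param al Axial length (mm).
#' @param acd Preoperative anterior chamber depth (mm).
#' @param r Mean anterior corneal radius (mm).
#' @param sa8 Spherical aberration at the 8.0 mm zone (um); required for
#'   `"modified-haigis-l"`.
#' @param implanted_power Implanted IOL power (D), optional.
#' @param postop_se Observed postoperative spherical equivalent (D), optional.
#' @param formula One of `"haigis"`, `"haigis-l"`, `"modified-haigis-l"`.
#' @param target_se Target refraction (D) for the IOL-power calculation.
#' @param constants [iol_constants()].
#' @param vd Vertex distance (mm).
#' @param keratometric_index Index for the plain-Haigis keratometric power.
#' @param model [pe_model()] for the modified formula.
#' @return A list with `formula`, `elp`, `corneal_power`, `iol_power`
#'   (power for `target_se`), and when available `predicted_se` and `pe`
#'   (observed minus predicted).
#' @export
#' @examples
#' predict_eye(28.43, 3.62, 8.79, formula = "haigis-l")$iol_power  # 22.37 D
predict_eye <- function(al, acd, r, sa8 = NULL,
                        implanted_power = NULL, postop_se = NULL,
                        formula = "haigis-l", target_se = 0,
                        constants = zcb00_constants(), vd = 12,
                        keratometric_index = 1.3315, model = pe_model()) {
  formula <- match.arg(formula, FORMULA_IDS)
  elp <- elp_haigis(acd, al, constants)
  z <- .corneal_power_for(formula, r, sa8, vd, keratometric_index, model)
  out <- list(formula = formula, elp = elp, corneal_power = z,
              iol_power = iol_power_for_target(al, elp, z, target_se, vd))
  if (!is.null(implanted_power)) {
    out$predicted_se <- predicted_refraction(implanted_power, al, elp, z, vd)
    if (!is.null(postop_se)) out$pe <- postop_se - out$predicted_se
  }
  out
}

#' Predict refraction for every eye of a cohort
#'
#' Vectorized per-cohort prediction. For each row of `cohort` computes the
#' formula's predicted spectacle-plane spherical equivalent for the
#' implanted power, and the prediction error
#' `pe = postop_se - predicted_se` (positive = hyperopic surprise) where
#' the observed outcome is present.
#'
#' @param cohort A cohort data frame in the schema of [read_cohort()] /
#'   [generate_cohort()]: columns `axial_length_mm`, `acd_mm`,
#'   `mean_corneal_radius_mm`, `implanted_power_d`, optionally `sa8_um`
#'   (required by the modified formula) and `postop_se_d`.
#' @inheritParams predict_eye
#' @return `cohort` with columns `predicted_se_d` and `pe_d` appended and
#'   attribute `"formula"` set.
#' @export
predict_cohort <- function(cohort, formula = "haigis-l",
                           constants = zcb00_constants(), vd = 12,
                           keratometric_index = 1.3315, model = pe_model()) {
  formula <- match.arg(formula, FORMULA_IDS)
  need <- c("axial_length_mm", "acd_mm", "mean_corneal_radius_mm",
            "implanted_power_d")
  if (formula == "modified-haigis-l") need <- c(need, "sa8_um")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("missing measurement: column '", missing_cols[1L],
         "' is required by the ", formula, " formula", call. = FALSE)
  if (nrow(cohort) == 0L) {
    cohort$predicted_se_d <- numeric(0)
    cohort$pe_d <- numeric(0)
    attr(cohort, "formula") <- formula
    return(cohort)
  }
  for (col in need)
    if (anyNA(cohort[[col]])) {
      bad <- which(is.na(cohort[[col]]))[1L]
      stop("missing measurement: '", col, "' is absent for case ",
           if ("eye_id" %in% names(cohort)) cohort$eye_id[bad] else bad,
           call. = FALSE)
    }
  elp <- elp_haigis(cohort$acd_mm, cohort$axial_length_mm, constants)
  z <- .corneal_power_for(formula, cohort$mean_corneal_radius_mm,
                          cohort$sa8_um, vd, keratometric_index, model)
  cohort$predicted_se_d <- predicted_refraction(
    cohort$implanted_power_d, cohort$axial_length_mm, elp, z, vd)
  cohort$pe_d <- if ("postop_se_d" %in% names(cohort))
    cohort$postop_se_d - cohort$predicted_se_d else NA_real_
  attr(cohort, "formula") <- formula
  cohort
}
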