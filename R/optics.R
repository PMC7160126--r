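# Thin-lens model-eye vergence arithmetic.
#
# All powers are in diopters (D), all distances in millimeters (mm).
# The aqueous/vitreous vergence numerator is fixed at 1336 (n = 1.336
# expressed per mm), as it appears in the Haigis vergence formula.

# denominators closer to zero than this are treated as singular
.SINGULAR_TOL <- 1e-9

.stop_singular <- function(what) {
  stop("singular vergence: ", what, call. = FALSE)
}

.check_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    stop("'", name, "' must be finite numeric", call. = FALSE)
  if (positive && any(x <= 0))
    stop("'", name, "' must be positive", call. = FALSE)
  invisible(x)
}

#' Haigis IOL constants
#'
#' Container for the lens-specific Haigis constants `a0`, `a1`, `a2` that
#' define the effective lens position `ELP = a0 + a1 * ACD + a2 * AL`.
#'
#' @param a0 Offset constant (mm).
#' @param a1 Coefficient on preoperative anterior chamber depth (per mm of ACD).
#' @param a2 Coefficient on axial length (per mm of AL).
#' @return A list of class `"iol_constants"` with elements `a0`, `a1`, `a2`.
#' @seealso [zcb00_constants()] for the ULIB-optimized Tecnis ZCB00 values.
#' @export
#' @examples
#' iol_constants(-1.302, 0.210, 0.251)
iol_constants <- function(a0, a1, a2) {
  .check_num(a0, "a0"); .check_num(a1, "a1"); .check_num(a2, "a2")
  structure(list(a0 = a0, a1 = a1, a2 = a2), class = "iol_constants")
}

#' ULIB-optimized Haigis constants for the Tecnis ZCB00 IOL
#'
#' @return An [iol_constants()] object with `a0 = -1.302`, `a1 = 0.210`,
#'   `a2 = 0.251`.
#' @export
zcb00_constants <- function() iol_constants(-1.302, 0.210, 0.251)

#' @export
print.iol_constants <- function(x, ...) {
  cat(sprintf("Haigis IOL constants: a0 = %g, a1 = %g, a2 = %g\n",
              x$a0, x$a1, x$a2))
  invisible(x)
}

#' Convert refraction between spectacle and corneal plane
#'
#' Vertex-distance transform of a refraction. `spectacle_to_corneal()`
#' maps a spectacle-plane refraction `REFs` to the corneal plane via
#' `REFc = 1000 * REFs / (1000 - REFs * vd)`; `corneal_to_spectacle()` is
#' its exact algebraic inverse. Both are vectorized.
#'
#' @param ref_s,ref_c Refraction (spherical equivalent) in diopters at the
#'   spectacle or corneal plane.
#' @param vd Vertex distance in mm (default 12).
#' @return Refraction in diopters at the other plane.
#' @export
#' @examples
#' spectacle_to_corneal(-1, 12)     # -0.98814
#' corneal_to_spectacle(spectacle_to_corneal(2, 12), 12)  # 2
spectacle_to_corneal <- function(ref_s, vd = 12) {
  .check_num(ref_s, "ref_s"); .check_num(vd, "vd", positive = TRUE)
  den <- 1000 - ref_s * vd
  if (any(den <= .SINGULAR_TOL))
    .stop_singular("1000 - ref_s * vd is zero or negative")
  1000 * ref_s / den
}

#' @rdname spectacle_to_corneal
#' @export
corneal_to_spectacle <- function(ref_c, vd = 12) {
  .check_num(ref_c, "ref_c"); .check_num(vd, "vd", positive = TRUE)
  den <- 1000 + ref_c * vd
  if (any(den <= .SINGULAR_TOL))
    .stop_singular("1000 + ref_c * vd is zero or negative")
  1000 * ref_c / den
}

#' Haigis effective lens position
#'
#' Predicted distance of the thin-lens IOL plane from the cornea:
#' `ELP = a0 + a1 * acd + a2 * al`. Unlike third-generation formulas the
#' Haigis ELP uses the measured preoperative anterior chamber depth, not
#' corneal power, so it is unaffected by prior corneal refractive surgery.
#'
#' @param acd Preoperative anterior chamber depth (mm, epithelium to lens).
#' @param al Axial length (mm).
#' @param constants An [iol_constants()] object; default [zcb00_constants()].
#' @return Effective lens position in mm.
#' @export
#' @examples
#' elp_haigis(3.62, 28.43)  # 6.59413
elp_haigis <- function(acd, al, constants = zcb00_constants()) {
  .check_num(acd, "acd", positive = TRUE)
  .check_num(al, "al", positive = TRUE)
  stopifnot(inherits(constants, "iol_constants"))
  constants$a0 + constants$a1 * acd + constants$a2 * al
}

#' IOL power for a target refraction (Haigis thin-lens formula)
#'
#' Power of the lens that, placed at `elp`, focuses the eye of axial length
#' `al` and effective corneal power `z` to the requested spectacle-plane
#' target refraction:
#' `P = 1336 / (al - elp) - 1336 / (1336 / z_eff - elp)`,
#' where `z_eff = z + REFc(target_ref_s)` adds the target's corneal-plane
#' vergence to the corneal power. With `target_ref_s = 0` this is exactly
#' the emmetropia formula.
#'
#' @param al Axial length (mm).
#' @param elp Effective lens position (mm), e.g. from [elp_haigis()].
#' @param z Effective corneal power (D); see [corneal_power_haigis_l()] and
#'   [corneal_power_modified()].
#' @param target_ref_s Target postoperative refraction at the spectacle
#'   plane (D); default 0 (plano).
#' @param vd Vertex distance (mm).
#' @return IOL power in diopters (continuous, not rounded to 0.5 D steps).
#' @export
#' @examples
#' iol_power_for_target(28.43, 6.59413, 32.57643)  # 22.366
iol_power_for_target <- function(al, elp, z, target_ref_s = 0, vd = 12) {
  .check_num(al, "al", positive = TRUE); .check_num(elp, "elp")
  .check_num(z, "z"); .check_num(target_ref_s, "target_ref_s")
  if (any(al <= elp))
    stop("geometry error: axial length must exceed effective lens position",
         call. = FALSE)
  z_eff <- z + spectacle_to_corneal(target_ref_s, vd)
  if (any(z_eff <= 0))
    .stop_singular("effective corneal power is zero or negative")
  den <- 1336 / z_eff - elp
  if (any(abs(den) < .SINGULAR_TOL))
    .stop_singular("1336 / z - elp is zero")
  1336 / (al - elp) - 1336 / den
}

#' Predicted refraction for an implanted IOL power
#'
#' Closed-form inverse of [iol_power_for_target()]: given the implanted
#' power, solve the thin-lens vergence chain for the spectacle-plane
#' refraction the model eye will have. The aphakic residual vergence is
#' `A = 1336 / (al - elp) - implanted_power`; the corneal power that would
#' make the implanted lens emmetropic is `z_req = 1336 * A / (1336 + A * elp)`
#' (continuous through `A = 0`); the corneal-plane refraction is
#' `z_req - z`, back-transformed to the spectacle plane.
#'
#' @param implanted_power Implanted IOL power (D).
#' @inheritParams iol_power_for_target
#' @return Predicted spherical equivalent (D) at the spectacle plane.
#' @export
#' @examples
#' predicted_refraction(20, 28.43, 6.59413, 32.57643)  # +1.618
predicted_refraction <- function(implanted_power, al, elp, z, vd = 12) {
  .check_num(implanted_power, "implanted_power")
  .check_num(al, "al", positive = TRUE); .check_num(elp, "elp")
  .check_num(z, "z")
  if (any(al <= elp))
    stop("geometry error: axial length must exceed effective lens position",
         call. = FALSE)
  a_verg <- 1336 / (al - elp) - implanted_power
  den <- 1336 + a_verg * elp
  if (any(abs(den) < .SINGULAR_TOL))
    .stop_singular("1336 + aphakic vergence * elp is zero")
  z_req <- 1336 * a_verg / den
  corneal_to_spectacle(z_req - z, vd)
}

#' Keratometric corneal power from radius
#'
#' Standard keratometric conversion `D = (n - 1) * 1000 / r` with a
#' configurable fictitious index, defaulting to the Haigis convention
#' n = 1.3315. This is the corneal power the plain Haigis formula uses; the
#' Haigis-L pipeline works on radii directly.
#'
#' @param r Anterior corneal radius of curvature (mm).
#' @param n Keratometric index (default 1.3315).
#' @return Corneal power in diopters.
#' @export
#' @examples
#' keratometric_power(7.5)           # 44.2 D with the 1.3315 convention
keratometric_power <- function(r, n = 1.3315) {
  .check_num(r, "r", positive = TRUE)
  .check_num(n, "n")
  if (any(n <= 1)) stop("keratometric index must exceed 1", call. = FALSE)
  (n - 1) * 1000 / r
}
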