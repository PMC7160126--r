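# Synthetic post-refractive-surgery cohort generator.
#
# The generator draws each biometric variable from an independent
# (optionally range-truncated) Gaussian, computes the Haigis-L IOL power
# for the target refraction as the implanted power, and constructs the
# observed postoperative refraction as the Haigis-L prediction plus a
# "true" prediction error that follows a linear function of SA8 plus
# Gaussian residual noise. Evaluating the Haigis-L formula on such a
# cohort therefore recovers the true prediction error exactly.

.GEN_VARS <- c("al", "acd", "r", "sa8", "sa6", "q6", "q8", "ecc6", "ecc8")

.var_spec <- function(mean, sd, range = NULL) {
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] < range[2])
    if (mean < range[1] || mean > range[2])
      stop("truncation range must contain the mean", call. = FALSE)
  }
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  list(mean = mean, sd = sd, range = range)
}

#' Parameters of the synthetic-cohort generator
#'
#' Each biometric variable is specified as `list(mean, sd, range)` where
#' `range` (optional) truncates the Gaussian by rejection resampling.
#' Defaults are the training-set marginals of a published post-myopic-
#' refractive-surgery cataract cohort; see [training_cohort_params()].
#'
#' @param n Number of eyes.
#' @param seed Root integer seed. Each variable and the residual noise use
#'   deterministic sub-streams derived from it, so adding or removing a
#'   variable does not perturb the draws of the others.
#' @param al,acd,r,sa8,sa6,q6,q8,ecc6,ecc8 Per-variable specs
#'   `list(mean =, sd =, range =)`; units mm (al, acd, r), um (sa8, sa6),
#'   dimensionless otherwise.
#' @param pe_model The true [pe_model()] used to construct prediction
#'   errors.
#' @param residual_sd SD (D) of the Gaussian residual added to the linear
#'   SA8 trend.
#' @param target_se Target refraction (D) used to choose each eye's
#'   implanted power (continuous Haigis-L power; default plano).
#' @param vd Vertex distance (mm).
#' @param constants [iol_constants()] used for the implanted-power and
#'   outcome construction.
#' @return A list of class `"cohort_params"`.
#' @export
cohort_params <- function(n = 80L, seed = 1L,
    al   = list(mean = 28.43, sd = 2.29, range = c(24.47, 33.45)),
    acd  = list(mean = 3.62, sd = 0.37, range = c(2.28, 4.73)),
    r    = list(mean = 8.79, sd = 0.53, range = c(7.82, 10.28)),
    sa8  = list(mean = 3.69, sd = 0.87, range = c(1.20, 5.49)),
    sa6  = list(mean = 1.16, sd = 0.39, range = c(0.24, 2.08)),
    q6   = list(mean = 1.57, sd = 0.70, range = c(0.03, 3.44)),
    q8   = list(mean = 0.82, sd = 0.58, range = c(-0.10, 2.66)),
    ecc6 = list(mean = -1.22, sd = 0.31, range = c(-1.85, -0.17)),
    ecc8 = list(mean = -0.82, sd = 0.39, range = c(-1.63, 0.32)),
    pe_model = haigisl::pe_model(), residual_sd = 0.45,
    target_se = 0, vd = 12, constants = zcb00_constants()) {
  stopifnot(n >= 0, inherits(pe_model, "pe_model"),
            inherits(constants, "iol_constants"))
  if (residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  vars <- list(al = al, acd = acd, r = r, sa8 = sa8, sa6 = sa6, q6 = q6,
               q8 = q8, ecc6 = ecc6, ecc8 = ecc8)
  vars <- lapply(vars, function(v) do.call(.var_spec, v))
  structure(c(vars, list(n = as.integer(n), seed = as.integer(seed),
                         pe_model = pe_model, residual_sd = residual_sd,
                         target_se = target_se, vd = vd,
                         constants = constants)),
            class = "cohort_params")
}

#' Default generator parameters: the training-set conditions
#'
#' The marginal means, SDs and observed ranges of the 80-eye training
#' cohort (axial length 28.43 +- 2.29 mm, ACD 3.62 +- 0.37 mm, mean
#' anterior corneal radius 8.79 +- 0.53 mm, SA8 3.69 +- 0.87 um, and so
#' on), with the published prediction-error regression
#' (slope 0.583 D/um, intercept -2.3488 D) as truth and residual SD
#' 0.45 D — the modified-formula error SD observed on that cohort.
#'
#' @param seed Root seed.
#' @param n Number of eyes (default 80, the training-set size).
#' @param truncate_sa8 If `FALSE`, the SA8 Gaussian is left untruncated so
#'   closed-form Gaussian expectations apply (used for calibration
#'   simulations); biometric ranges stay truncated either way.
#' @return A [cohort_params()] object.
#' @export
training_cohort_params <- function(seed = 1L, n = 80L, truncate_sa8 = TRUE) {
  p <- cohort_params(n = n, seed = seed)
  if (!truncate_sa8) p$sa8$range <- NULL
  p
}

# truncated-normal draw by rejection resampling; proper distribution,
# no boundary atoms
.rtrunc_norm <- function(n, mean, sd, range = NULL) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  if (is.null(range)) return(x)
  if (range[2] < mean - 6 * sd || range[1] > mean + 6 * sd)
    stop("infeasible truncation: range lies beyond 6 sd of the mean",
         call. = FALSE)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

#' Generate a synthetic post-refractive-surgery cohort
#'
#' Draws per-eye biometry from the parameter marginals (independently;
#' only marginal information is available for the emulated cohort), sets
#' each implanted power to the continuous Haigis-L power for the target
#' refraction, and constructs the observed outcome as
#' `postop_se = Haigis-L predicted SE + true_pe` with
#' `true_pe = pe_model(SA8) + N(0, residual_sd)`.
#' Identical `(params, seed)` give bit-identical cohorts.
#'
#' @param params A [cohort_params()] object.
#' @return A data frame with columns `eye_id`, `axial_length_mm`,
#'   `acd_mm`, `mean_corneal_radius_mm`, `sa8_um`, `sa6_um`, `q6`, `q8`,
#'   `ecc6`, `ecc8`, `implanted_power_d`, `postop_se_d`, and the
#'   generator-bookkeeping column `true_pe_d` (absent in real data).
#' @export
#' @examples
#' cohort <- generate_cohort(training_cohort_params(seed = 42))
#' head(cohort)
generate_cohort <- function(params = training_cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n
  # fixed-length sub-seed table: one stream per variable plus one for the
  # residual noise, all derived from the root seed
  set.seed(params$seed)
  sub_seeds <- sample.int(2147483646L, length(.GEN_VARS) + 1L)
  draws <- vector("list", length(.GEN_VARS))
  names(draws) <- .GEN_VARS
  for (i in seq_along(.GEN_VARS)) {
    v <- params[[.GEN_VARS[i]]]
    set.seed(sub_seeds[i])
    draws[[i]] <- .rtrunc_norm(n, v$mean, v$sd, v$range)
  }
  set.seed(sub_seeds[length(sub_seeds)])
  noise <- stats::rnorm(n, 0, params$residual_sd)

  elp <- if (n) elp_haigis(draws$acd, draws$al, params$constants) else numeric(0)
  z <- if (n) corneal_power_haigis_l(draws$r) else numeric(0)
  implanted <- if (n) iol_power_for_target(draws$al, elp, z,
                                           params$target_se, params$vd)
               else numeric(0)
  predicted <- if (n) predicted_refraction(implanted, draws$al, elp, z,
                                           params$vd) else numeric(0)
  true_pe <- if (n) pe_from_sa(draws$sa8, params$pe_model) + noise
             else numeric(0)

  data.frame(eye_id = sprintf("eye_%03d", seq_len(n)),
             axial_length_mm = draws$al,
             acd_mm = draws$acd,
             mean_corneal_radius_mm = draws$r,
             sa8_um = draws$sa8,
             sa6_um = draws$sa6,
             q6 = draws$q6, q8 = draws$q8,
             ecc6 = draws$ecc6, ecc8 = draws$ecc8,
             implanted_power_d = implanted,
             postop_se_d = predicted + true_pe,
             true_pe_d = true_pe,
             stringsAsFactors = FALSE)
}
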