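---
title: "IOL power after myopic laser surgery: the Haigis-L formula and its spherical-aberration correction"
author: "haigisl package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IOL power after myopic laser surgery: the Haigis-L formula and its spherical-aberration correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haigisl)
```

## The clinical problem

Cataract surgery replaces the crystalline lens with an intraocular lens
(IOL) whose power must be chosen preoperatively so the eye ends up near
the refractive target. Standard formulas work well on virgin corneas, but
eyes that underwent myopic PRK or LASIK break two of their assumptions:
keratometry misreads the flattened central cornea, and the fictitious
keratometric index no longer captures the anterior/posterior curvature
ratio after ablation. The net effect is an overestimated corneal power
and therefore an underpowered IOL — a hyperopic surprise, in exactly the
patients with the highest expectations.

The Haigis-L approach repairs this without historical data: it predicts
the effective lens position (ELP) from anterior chamber depth and axial
length only (so prior corneal surgery cannot corrupt it) and replaces
keratometric corneal power by a regression on the measured anterior
corneal radius. What Haigis-L still ignores is *how much* ablation each
cornea received. Myopic ablation makes the cornea oblate, and the induced
anterior-corneal spherical aberration over a wide (8.0 mm) zone grows
with the treated refractive change. This package implements a further
correction that uses that spherical aberration, measured with a
Scheimpflug camera before cataract surgery, to absorb the
ablation-dependent part of the Haigis-L prediction error.

## The model

All powers are diopters (D), distances millimeters (mm), spherical
aberration micrometers (µm). Three ingredients:

**Thin-lens vergence formula.** With axial length $AL$, effective lens
position $d$ and effective corneal power $Z$, the emmetropizing IOL power
is
$$P \;=\; \frac{1336}{AL - d} \;-\; \frac{1336}{\dfrac{1336}{Z} - d},$$
with 1336 the aqueous/vitreous refractive index expressed per mm. The
Haigis ELP is $d = a_0 + a_1\,\mathrm{ACD} + a_2\,AL$; the package ships
the ULIB-optimized constants for the Tecnis ZCB00
(`zcb00_constants()`: $a_0=-1.302$, $a_1=0.210$, $a_2=0.251$). A nonzero
target refraction is handled by adding its corneal-plane vergence to $Z$,
which reduces bit-exactly to the formula above at plano.
`predicted_refraction()` is the closed-form inverse — the refraction an
implanted power will produce — written as
$Z_{req} = 1336A/(1336 + A d)$ with $A = 1336/(AL-d) - P$ so it is
continuous through $A = 0$.

**Plane transforms.** Refractions move between spectacle and corneal
plane with vertex distance $VD = 12$ mm:
$$REF_c = \frac{1000\,REF_s}{1000 - REF_s \cdot VD},$$
and `corneal_to_spectacle()` is the exact algebraic inverse. Denominators
within $10^{-9}$ of zero (or of the wrong sign) raise a singular-vergence
error rather than returning huge values.

**Corneal power conventions.** Three interchangeable choices of $Z$
define the three formulas:

* `haigis`: keratometric power $(n-1) \cdot 1000/r$, default
  $n = 1.3315$ (configurable). Present as the uncorrected baseline.
* `haigis-l`: the regression-corrected effective power
  $Z = -5.6125\,r + 82.2603 - 0.35$, which absorbs the post-ablation
  radius and index biases; the constant $-0.35$ D offset (attributed to
  residual lens-position error) lives inside the corneal power, not in
  the final refraction.
* `modified-haigis-l`: the spherical-aberration correction. The expected
  Haigis-L prediction error is modeled as a line in the 8.0 mm-zone
  spherical aberration, $\widehat{PE} = \beta_1 SA_{8} + \beta_0$
  (defaults $\beta_1 = 0.583$ D/µm, $\beta_0 = -2.3488$ D), and its
  corneal-plane equivalent is subtracted from the Haigis-L power:
  $$Z' = Z_{\text{Haigis-L}} - REF_c(\widehat{PE}).$$
  A positive expected error (hyperopic surprise) lowers $Z'$ and raises
  the computed power. The correction is deliberately applied at the
  corneal plane inside $Z$, not as a spectacle-plane shift of the final
  prediction; at a plano operating point the two agree exactly, away
  from it they differ at second order in $VD \cdot REF_c / 1000$.

Prediction error is everywhere defined as observed postoperative
spherical equivalent minus predicted (positive = hyperopic surprise),
and IOL power is treated as continuous in evaluation — the half-diopter
display rounding (`--round_step` on the CLI) never enters computation.

## Calibration

`sa_calibrate()` is the package's fitting function. Given a training
cohort with implanted powers and observed outcomes it scores every eye
under Haigis-L, regresses the prediction error on $SA_8$ by ordinary
least squares, and returns an `"sa_fit"` object whose `pe_model` drives
the modified formula; `print`, `summary`, `coef`, `predict`,
`residuals`, `plot` and `simulate` behave as for any fitted model.
The correlation screen (`correlate_predictors()`) reports Pearson r with
a two-sided t test on $n-2$ degrees of freedom for each biometric
predictor; in both the emulated cohort and its source, $SA_8$ dominates
(r ≈ 0.75) while axial length, ACD and radius are uncorrelated with the
error. The regression deliberately uses $SA_8$ alone: the weaker
predictors (Q-values, eccentricities, $SA_6$) are screened but not
modeled, and train/test splitting is the caller's responsibility —
`sa_calibrate()` never sees held-out data.

One documented quirk is inherited deliberately: the published
coefficients do not place the line through the published training means
($0.583 \times 3.69 - 2.3488 = -0.198$ D, while the reported Haigis-L
mean error is $-0.05$ D). An OLS line must pass through the centroid, so
those three printed numbers cannot all be exact. The package keeps the
printed coefficients as defaults and does not arbitrate; consequently the
Haigis-L mean error is not a quantity the simulation is expected to
reproduce.

## The synthetic-cohort generator

No patient-level data accompany the study this package emulates, so
`generate_cohort()` builds cohorts that reproduce its *reported*
structure:

* Each biometric variable is an independent Gaussian with the
  training-set mean and SD (AL 28.43 ± 2.29 mm, ACD 3.62 ± 0.37 mm,
  radius 8.79 ± 0.53 mm, $SA_8$ 3.69 ± 0.87 µm, plus $SA_6$, Q-values
  and eccentricities), truncated to the reported ranges by rejection
  resampling — a proper truncated distribution, with no boundary atoms
  that clipping would create. Only marginals are reported, so variables
  are drawn independently; real biometry is correlated (long eyes tend
  to deeper chambers and flatter, heavily ablated corneas), which is the
  main feature the generator does not emulate.
* The implanted power is the continuous Haigis-L power for the target
  refraction (default plano — per-case targets are unreported, and this
  choice makes the corneal-plane correction round-trip exactly).
* The observed outcome is constructed as Haigis-L prediction plus a true
  error $0.583\,SA_8 - 2.3488 + \varepsilon$,
  $\varepsilon \sim N(0, 0.45)$ D, the residual SD being the modified
  formula's reported error SD.
* One root seed spawns a fixed table of per-variable sub-streams, so the
  same seed gives bit-identical cohorts and adding or removing a
  variable never perturbs the others' draws.

This design makes two wiring identities hold by construction, and the
test suite asserts them to $10^{-9}$ D: scoring a generated cohort with
Haigis-L returns exactly the generator's true error, and scoring it with
the modified formula returns exactly the residual $\varepsilon$.

What passing these simulations shows — and what it does not. The
reported summary numbers are mutually consistent under this generative
model: $0.583 \times 0.87 \approx 0.51 \approx \sqrt{0.68^2 - 0.45^2}$,
so a Gaussian $SA_8$ with the reported regression and residual reproduces
the slope, correlation (≈ 0.75), both error SDs, and both MAEs. The
package's simulations (200 replicates of n = 80, seconds of runtime)
recover all of these; that validates the implementation and the internal
consistency of the reported numbers, not the clinical performance of the
correction on real eyes, which only prospective data can establish.

## Numerical and design choices

* Quantiles use linear interpolation between order statistics
  (`quantile` type 7) and the within-0.5/1.0/1.5 D percentages use
  inclusive comparison; neither convention is dictated by the emulated
  study, both are fixed here for reproducibility. SDs are the $n-1$
  sample SD throughout.
* Singular-denominator tolerance $10^{-9}$; geometry ($AL \le ELP$) and
  singular-vergence conditions raise errors instead of returning
  unphysical values. With ELP and corneal power held fixed, IOL power
  decreases in axial length ($\partial P/\partial AL =
  -1336/(AL-ELP)^2$) and in corneal power; both monotonicities are
  verified numerically.
* The OLS fit and Pearson test are delegated to `stats::lm()` and
  `stats::cor.test()`; the test suite checks both against independent
  explicit-sum oracles.
* Cohorts travel as a flat CSV (columns `eye_id`, `axial_length_mm`, …,
  `postop_se_d`), with the generator's `true_pe_d` column clearly
  bookkeeping-only. Unknown columns pass through untouched; biometry is
  validated against physical bounds on read.

## A worked eye

The training-set mean eye (AL 28.43 mm, ACD 3.62 mm, radius 8.79 mm,
$SA_8$ 3.69 µm):

```{r worked}
elp_haigis(3.62, 28.43)                 # ELP, mm
corneal_power_haigis_l(8.79)            # Haigis-L Z, D
corneal_power_modified(8.79, 3.69)      # SA-corrected Z', D
predict_eye(28.43, 3.62, 8.79, formula = "haigis-l")$iol_power
predict_eye(28.43, 3.62, 8.79, sa8 = 3.69,
            formula = "modified-haigis-l")$iol_power
```

The expected Haigis-L error at this $SA_8$ is slightly myopic
(`pe_from_sa(3.69)` ≈ −0.20 D), so the corrected formula asks for about
0.28 D less IOL power.

## End-to-end simulation

```{r sim}
cohort <- generate_cohort(training_cohort_params(seed = 42))
fit <- sa_calibrate(cohort)
fit
compare_formulas(cohort)
```

## Limitations

Beyond the independence of the simulated marginals, the generator does
not model device measurement noise, astigmatism (predictions are
spherical-equivalent only), thick-lens or ray-tracing optics, or the
external comparator formulas (Barrett True-K, Shammas-PL) whose
internals are not public. The shipped regression defaults come from a
single-center, single-IOL (ZCB00) retrospective cohort; recalibration
with `sa_calibrate()` on local data is the intended path to other lenses
and populations.
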