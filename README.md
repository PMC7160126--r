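# haigisl

IOL power calculation for eyes with prior myopic laser refractive
surgery (PRK/LASIK), for ophthalmic biometry researchers and formula
developers. The package implements the Haigis thin-lens formula, the
Haigis-L corneal-power correction, and a **modified Haigis-L formula**
whose effective corneal power is additionally corrected by the
anterior-corneal spherical aberration measured over the 8.0 mm zone —
the quantity that tracks how much ablation a cornea received and,
with it, the residual error Haigis-L makes.

## The model

With axial length *AL* (mm), Haigis effective lens position
*ELP = a₀ + a₁·ACD + a₂·AL*, and effective corneal power *Z* (D):

    IOL power = 1336/(AL − ELP) − 1336/(1336/Z − ELP)

The three corneal-power conventions select the formula:

| formula id          | effective corneal power Z                          |
|---------------------|----------------------------------------------------|
| `haigis`            | keratometric, (n − 1)·1000/r, n = 1.3315           |
| `haigis-l`          | −5.6125·r + 82.2603 − 0.35                         |
| `modified-haigis-l` | Haigis-L Z − REFc(0.583·SA₈ − 2.3488)              |

where REFc(x) = 1000·x/(1000 − 12·x) moves the expected prediction
error from the spectacle to the corneal plane. Prediction error is
observed minus predicted spherical equivalent (positive = hyperopic
surprise). The correction's coefficients can be refit on local data
with `sa_calibrate()`, the package's central fitting function, which
returns a classed model object with the usual `print`/`summary`/
`coef`/`predict`/`residuals`/`plot`/`simulate` methods.

Because no patient-level data are public for this problem, the package
includes a seeded synthetic-cohort generator (`generate_cohort()`)
reproducing the reported training-set marginals and error structure, so
every pipeline stage is testable end to end.

## Worked example

The training-set mean eye — AL 28.43 mm, ACD 3.62 mm, mean anterior
corneal radius 8.79 mm, SA₈ 3.69 µm:

```r
library(haigisl)
elp_haigis(3.62, 28.43)
#> [1] 6.59413
corneal_power_haigis_l(8.79)
#> [1] 32.576425
predict_eye(28.43, 3.62, 8.79, formula = "haigis-l")$iol_power
#> [1] 22.365844
predict_eye(28.43, 3.62, 8.79, sa8 = 3.69, formula = "modified-haigis-l")$iol_power
#> [1] 22.08571
```

The lens sits an estimated 6.59 mm behind the cornea; Haigis-L assigns
the post-LASIK cornea 32.58 D and asks for a 22.37 D lens for plano.
At SA₈ = 3.69 µm the correction expects a −0.20 D (myopic) Haigis-L
error, so the modified formula asks for ~0.28 D less power. On a
synthetic cohort the two formulas separate exactly as designed:

```r
cohort <- generate_cohort(training_cohort_params(seed = 42))
compare_formulas(cohort)
#>      statistic haigis-l modified-haigis-l
#>              n    80.00             80.00
#>             me    -0.05              0.10
#>             sd     0.66              0.41
#>   median_error    -0.08              0.13
#>            mae     0.55              0.36
#>          sd_ae     0.36              0.23
#>      median_ae     0.46              0.32
#>            iqr     0.99              0.63
#>  pct_within_05    55.00             68.75
#>  pct_within_10    85.00            100.00
#>  pct_within_15    98.75            100.00
```

The spherical-aberration correction roughly halves the error SD and
brings every eye within 1.0 D of target.

A command-line calculator wraps the same functions
(`exec/haigisl`, or `run_cli()` in R):

```sh
haigisl calc --al 28.43 --acd 3.62 --r 8.79 --formula haigis-l --target 0
haigisl simulate --n 80 --seed 1 --out cohort.csv
haigisl calibrate --cohort cohort.csv
haigisl evaluate --cohort cohort.csv
```

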