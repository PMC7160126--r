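Package: haigisl
Title: IOL Power Calculation After Myopic Laser Refractive Surgery with a
    Spherical-Aberration-Corrected Haigis-L Formula
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Thin-lens intraocular lens (IOL) power calculation for eyes
    with prior myopic PRK or LASIK. Implements the Haigis vergence formula
    with effective lens position from the a0/a1/a2 constants, the Haigis-L
    regression correction of measured corneal radius, and a modified
    Haigis-L formula that further corrects effective corneal power using
    anterior-corneal spherical aberration measured over the 8.0 mm zone.
    Includes calibration of the spherical-aberration correction from a
    cohort (prediction error regressed on spherical aberration), refractive
    prediction-error summaries (mean error, mean absolute error, medians,
    interquartile range, percentage of eyes within 0.5/1.0/1.5 D), a
    seeded synthetic-cohort generator for testing without patient data,
    cohort CSV input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
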