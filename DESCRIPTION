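Package: uvealrad
Title: Quantification of Radiation-Induced DNA Damage in Uveal Melanoma Histology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying DNA damage in brightfield
    histology of uveal melanoma and relating it to chromosome 3 status and
    radiotherapy regimen. Provides Beer-Lambert colour deconvolution of
    TUNEL-stained sections into stain concentration maps, Otsu-style
    thresholding and pooled TUNEL-positive area fractions, cohort-relative
    monosomy 3 calling from per-cell FISH signal counts, histopathological
    marker quantification (vessel area, macrophage density, morphology and
    necrosis categories), nonparametric cohort statistics (tie-corrected
    Mann-Whitney U, exact Fisher tests, Kaplan-Meier with Greenwood intervals,
    log-rank), a seeded synthetic-data generator with known ground truth, and
    a command-line interface tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
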