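Package: bonemat
Title: Bone Material Quality Analysis from qBEI Images and Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for bone material quality at the tissue level:
    calibration of quantitative backscattered electron (qBEI) grey-level images
    to local calcium concentrations, bone mineralization density distribution
    (BMDD) histograms and their five derived parameters against a pooled healthy
    reference, segmentation and ellipse morphometry of osteocyte lacunae
    sections (OLS), Raman spectral preprocessing (trimming, rubber-band
    fluorescence baseline) with five band-ratio bone-quality metrics, and the
    assumption-gated statistical comparison workflow (Shapiro-Wilk and
    Brown-Forsythe gated parametric/nonparametric tests with post-hoc
    procedures). Includes a synthetic phantom and spectrum generator with
    analytic ground truth for validation of every downstream parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    png
Config/testthat/edition: 3
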