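Package: qustr
Title: Quantitative Ultrasound Spectral Analysis of Tumor Response to Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring tumor response to chemotherapy with
    calibrated backscatter spectral analysis of radio-frequency (RF)
    ultrasound. Computes quartz-flat calibrated power spectra over gated
    regions of interest and extracts the two standard linear-regression
    biomarkers, spectral slope (dB/MHz) and midband fit (dB); counts
    hematoxylin-stained nuclei in H&E fields by HSI-threshold segmentation,
    area/aspect filtering and watershed splitting of touching cells; and
    links both to treatment status through group statistics and
    leave-one-out cross-validated linear-discriminant classification.
    Includes a seeded point-scatterer RF simulator and a synthetic H&E
    field generator with exact ground truth, so the full acquisition ->
    spectra -> histology -> statistics pipeline can be exercised and
    validated end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    EBImage,
    png,
    MASS,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
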