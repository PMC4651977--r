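Package: plaquerep
Title: Scan-Rescan Repeatability of Automated Carotid Plaque Component
    Classification from Multi-Contrast Vessel-Wall MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates paired scan/rescan multi-contrast (T1w, T2w, PDw,
    TOF) carotid vessel-wall MRI cohorts with ground-truth plaque-component
    labels and an imperfect manual observer; classifies vessel-wall pixels
    into plaque components (fibrous tissue, lipid, calcification, loose
    matrix) with a Gaussian linear discriminant over normalized-intensity,
    scale-space derivative and wall-geometry features, evaluated by
    leave-one-patient-out cross-validation with isolated-pixel
    post-processing; and quantifies scan-rescan repeatability of the
    resulting component areas via Spearman correlation, Bland-Altman
    coefficients of repeatability, Levene variance comparison, Wilcoxon
    matched-pairs and D'Agostino-Pearson tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
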