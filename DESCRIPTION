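Package: dwiqc
Title: Quality Control and QIBA Conformance for Quantitative Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end standardization workflow for diffusion-weighted MRI
    (DWI) and apparent diffusion coefficient (ADC) quantification. Simulates
    multi-vial diffusion phantom exams with Rician noise and longitudinal
    patient ROI data, fits voxelwise ADC maps by log-linear or two-point
    mono-exponential models, computes the QIBA DWI performance metrics
    (ADC bias, repeatability coefficient and within-subject CV, linearity,
    b-value dependence, random measurement error, SNR by the difference
    method), checks them against the QIBA claims and tiered acquisition
    protocol specifications, and runs patient-stage quality assurance
    (image-quality scorecards, tissue ROI repeatability, CSF versus
    body-temperature water comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
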