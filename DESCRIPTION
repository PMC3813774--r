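Package: fgrkit
Title: Analysis Toolkit for Mouse Fetal Growth Restriction Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of mouse fetal growth
    restriction (FGR) intervention studies in which growth-restricted and
    wild-type pups coexist within litters. Provides a litter-structured
    synthetic cohort generator; one-phase exponential fitting of maternal
    plasma radiotracer disappearance curves and unidirectional maternofetal
    clearance (Kmf) computation; Gaussian fetal-weight distribution fitting
    with 5th-centile classification; umbilical Doppler waveform cycle
    detection and pulsatility index extraction; litter-aware permutation
    inference with step-down Sidak multiple-comparison adjustment; and
    drinking-water dosing arithmetic. All user-facing functions take and
    return tidy data frames.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
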