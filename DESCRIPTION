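Package: oligostate
Title: Multi-Technique Oligomeric-State Analysis for Protein Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for inferring the oligomeric state of
    protein assemblies from complementary biophysical evidence. Implements
    small-angle X-ray scattering reductions (Guinier and cross-sectional
    Guinier fits, dimensionless Kratky transform, Tikhonov-regularized
    indirect Fourier transform to the pair-distance distribution, analytic
    form-factor models and fitting, excluded-volume molecular-weight
    estimation), MALDI-TOF oligomer series assignment against an n*M mass
    ladder with charge-state deconvolution, AFM height-map particle
    morphometry with per-class Gaussian statistics, ITC injection-peak
    integration with temperature-trend assessment, and a cross-technique
    stoichiometry reconciliation report. Ships seeded synthetic-data
    generators that emulate each instrument so the whole pipeline is testable
    without raw instrument data.
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
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    patchwork,
    knitr
Config/testthat/edition: 3
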