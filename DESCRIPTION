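Package: atrialstasis
Title: Desk-Scale Simulation of Left Atrial Blood Stasis from Chamber Wall Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies blood stasis in the left atrium (LA) and left atrial
    appendage (LAA) from chamber wall motion alone. Provides a synthetic
    generator of moving LA + LAA + LV chamber geometries with prescribed
    ejection fractions and periodic volume waveforms, surface motion tracking
    by non-rigid iterative closest point registration, morphological and
    functional descriptors (chamber volumes, ejection fractions, peak
    transvalvular flow rates, the LA retention ratio), a moving-boundary
    incompressible flow solver driven purely by endocardial motion with
    pressure openings and binary valve states, a residence-time transport
    equation solved as a passive scalar on the computed flow, and a cohort
    statistics layer (two-sample t-tests, univariate regression with
    confidence bands and leave-one-out leverage reports) for comparing
    atrial-fibrillation-like and control-like groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RANN,
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    grDevices,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
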