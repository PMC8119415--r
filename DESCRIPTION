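Package: cardiomapr
Title: Automated Action Potential Analysis for Optical Mapping of Cardiac Microtissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing optical-mapping recordings of paced 3D
    human cardiac microtissues loaded with a voltage-sensitive dye. Turns a
    fluorescence movie stack into per-microtissue action-potential traces by
    spectral (pacing-band) active-pixel detection, thresholding and
    connected-component segmentation; computes eight per-beat pro-arrhythmia
    metrics (excitability, stimulation delay, rise time, APD30/50/80,
    APD to maximum repolarization rate, triangulation, early-afterdepolarization
    flag); and provides study-level statistics: nested variance decomposition
    across beat/tissue/mold/batch replicates, dose-response sigma-shift and
    signature maps, restitution curves, power analysis and a slope-equality
    Z-test for the triangulation-based hERG-block indicator. Includes a
    ground-truthed synthetic-data generator (parametric AP waveforms, rendered
    movies, hierarchical APD sets) and a minimal ventricular ionic model for
    property-level validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    signal,
    tiff,
    nortest,
    EBImage,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
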