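Package: frapflow
Title: Diffusive and Convective Tracer Transport Analysis for Brain Extracellular Space Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and analyse solute transport in brain parenchyma
    from fluorescence microscopy. Provides closed-form diffusion-equation
    predictions of tracer penetration (semi-infinite surface source and
    point-source geometries), a finite-difference convection-diffusion
    simulator with photobleaching initial conditions, analysis of
    fluorescence recovery after photobleaching (FRAP) stacks including
    recovery half-times, quadrant asymmetry, bleach-spot centroid tracking
    and a null-calibrated convective-velocity upper bound, quantification of
    tracer distribution in section images (threshold fractional area, depth,
    radial and line profiles with exposure bridging), and a synthetic
    microscopy generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
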