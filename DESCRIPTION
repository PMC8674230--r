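Package: capflowr
Title: Quantifying Protein Liquid-Liquid Phase Separation from
    Capillary-Flow Fluorescence Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of capillary-flow fluorescence experiments for
    quantitative characterization of protein liquid-liquid phase
    separation (LLPS).  A continuously injected sample flows past a
    fluorescence detector: the dilute phase sets a flat baseline
    (convertible to concentration through a standard curve) while
    condensate droplets pass as signal spikes.  The package provides
    standard-curve calibration, sigmoid-front/baseline extraction and
    dilute-phase quantification, spike detection, droplet-formation
    kinetics with an asymmetric least squares baseline, Taylor-dispersion
    hydrodynamic radii and cooperative binding-isotherm fits, relative
    enrichment factors, relative droplet-size distributions through a
    Poiseuille-flow intensity model, closed-form capillary flow physics,
    and a physics-based trace simulator with known ground truth so every
    analysis stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
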