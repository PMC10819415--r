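Package: mpdeep
Title: Signal-to-Background Modelling and Image-Stack Analysis for
    Two- and Three-Photon Deep Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for planning and analysing deep multiphoton (two- and
    three-photon) fluorescence imaging of densely fluorescent samples such
    as bacterial mycelium. Implements a Gaussian-beam excitation model with
    exponential ballistic scattering loss that predicts the
    signal-to-background ratio as a function of imaging depth, scattering
    length and excitation order; histogram-based z-stack analysis
    (background mode, threshold signal, depth profiles); least-squares
    estimation of excitation nonlinearity exponents and effective
    attenuation lengths; point-spread-function fitting from bead stacks;
    and a synthetic phantom generator (filament scenes, bead stacks, power
    series) that renders volumes through the same optics model so every
    analysis stage can be exercised end to end without microscope data.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    withr
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
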