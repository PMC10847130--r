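Package: poreforce
Title: Force-Interplay Modelling of Micropollutant Transport in Slippery Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the transport and adsorption of steroid-hormone
    micropollutants inside slippery nanopores such as the inner channels of
    vertically aligned carbon nanotube (VaCNT) membranes. Implements
    slip-corrected Hagen-Poiseuille pore hydraulics with slip-length and
    flow-enhancement inversion, transport timescales (Peclet number,
    hydraulic residence time, Stokes-Einstein diffusivity), the four-force
    balance on a confined solute (hydrodynamic drag, sphere-wall van der
    Waals adhesion, short-range repulsion, wall friction) with an
    adsorption-regime classifier, mass-balance analysis of breakthrough
    curves including support-membrane subtraction and uncertainty
    propagation, and a seeded synthetic breakthrough-curve generator with
    closed-form ground truth for end-to-end validation.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
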