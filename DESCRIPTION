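Package: irkwall
Title: Monte Carlo Wall Correction Factors for Ir-192 Air-Kerma Standard
    Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale Monte Carlo photon transport simulator for
    primary-standard dosimetry of high-dose-rate Ir-192 brachytherapy
    sources. Computes the wall correction factor k_wall and its
    attenuation (k_att) and scatter (k_sc) components for spherical
    graphite-walled cavity ionization chambers using a track-length
    collision-kerma estimator under the kerma approximation, builds the
    capsule-attenuated Ir-192 fluence spectrum at the reference air-kerma
    rate measurement point, and assesses dose perturbation when the
    source is displaced inside a cylindrical air cavity in a PMMA
    phantom. Ships log-log interpolated photon interaction coefficient
    tables for the relevant media and a fixture generator for fictitious
    materials with closed-form transport answers.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
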