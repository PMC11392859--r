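Package: thinfil
Title: Stochastic Markov Modeling of Cardiac Thin-Filament Activation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates calcium regulation of the cardiac thin filament as a
    chain of coupled 24-state Markov regulatory units (troponin C calcium
    site, troponin I switch and inhibitory peptides, and tropomyosin in its
    blocked/closed/open azimuthal positions), with nearest-neighbor
    tropomyosin coupling. Provides an exact master-equation oracle for short
    chains, an event-driven stochastic ensemble simulator for the full
    26-unit filament, steady-state force-pCa protocols with Hill fitting,
    isometric twitch protocols driven by parametric calcium transients,
    twitch-metric extraction (peak force, TTP, RT50, nFTI), grid-search
    fitting of mutation-induced changes in tropomyosin chain stiffness and
    B-to-C equilibrium, expression-level sweeps and inference of mutant
    expression from twitch phenotypes, bootstrap group comparison, and
    synthetic-data generators for in vitro motility and engineered-heart-
    tissue style measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
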