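Package: boutonnet
Title: Longitudinal Axonal Bouton Dynamics and a Spiking-Network Model of
    Injury and Synaptic Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying longitudinal en passant bouton (EPB)
    dynamics from in vivo axon-tracking tables (density, turnover rate,
    gains/losses, size ratios, stability classes, close/far splits) and for
    quantifying axon degeneration, retraction and regeneration after a
    focal lesion, together with a recurrent excitatory leaky
    integrate-and-fire network with rate-based Hebbian plasticity that
    links measured synaptic turnover to associative-memory performance.
    Includes a seeded synthetic-data generator for bouton tracks and
    lesioned-axon cohorts, a staged lesion-and-rewiring model of the
    weight matrix, learning-rate calibration against experimental
    turnover ratios, and baseline/injury experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
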