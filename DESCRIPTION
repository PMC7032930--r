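Package: dgsep
Title: Feedback-Inhibition Microcircuit Model and Pattern-Separation Analysis for the Dentate Gyrus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based spiking model of a dentate gyrus lamella
    (granule cells, basket cells, hilar perforant-path-associated cells and
    mossy cells) with Tsodyks-Markram short-term facilitation on mossy-fiber
    outputs, together with the full in-silico pattern-separation pipeline:
    theta/gamma-modulated inhomogeneous-Poisson perforant-path input
    patterns with graded overlap, tuning-phase physiology protocols
    (recruitment curves, spatial inhibition profiles, facilitation-index
    train stimulation), population rate-vector similarity statistics
    (Pearson R, cosine/NDP, overlap), binwise separation curves, isolated
    condition effects and robustness scans, plus a surrogate-data generator
    for testing the statistics layer without the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
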