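Package: striatnet
Title: Striatal Microcircuit Network Model with Lateral and Feedforward Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and simulation of a spatial striatal network of
    medium spiny neurons (MSNs) and fast-spiking interneurons (FSIs).
    Provides multicompartment morphology scaffolds, distance-gated stochastic
    connectivity with empirically constrained contact counts and delays, a
    jitter-and-shift generator for partially synchronized synaptic input
    trains, a reduced-biophysics network simulator (passive cable with a
    spiking-soma surrogate, two-state conductance synapses, event-driven
    delays), and analysis procedures for inhibitory postsynaptic potentials
    (paired-subtraction extraction, double-exponential fitting with an
    R-squared filter and one-sample z-test) and peri-event suppression
    statistics, so the functional consequences of lateral (MSN-to-MSN) and
    feedforward (FSI-to-MSN) GABAergic inhibition can be studied at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
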