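Package: golgicell
Title: Multicompartmental Models of Cerebellar Golgi Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based multicompartmental modeling of cerebellar Golgi
    cells. Reads and synthesizes SWC morphologies, distributes Hodgkin-Huxley
    and Markov ion channels with submembrane calcium dynamics over soma,
    dendrites, axon initial segment and axon, and integrates the cable
    equation implicitly with a compiled Hines solver. Includes Tsodyks-Markram
    dynamic synapses with AMPA, NMDA and GABA-A receptor kinetics, a battery
    of electrophysiological protocols (pacemaking, frequency-intensity, sag,
    rebound, phase reset, resonance, synaptic thresholds, PSTH), evolutionary
    optimization of maximum conductances against spike-feature templates with
    staged validation, and a calcium-threshold predictor of spike-timing
    dependent plasticity at mossy fiber synapses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    patchwork
Config/testthat/edition: 3
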