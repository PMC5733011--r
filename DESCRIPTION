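Package: resplast
Title: Recurrent Spiking Reservoirs with Combined Hebbian and Heterosynaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of liquid-state-machine style reservoirs of
    leaky integrate-and-fire neurons trained with two weight-dependent
    spike-timing-dependent plasticity rules (a power-law rule for input
    synapses and an exponential rule for recurrent excitatory synapses)
    combined with a non-Hebbian heterosynaptic decay toward a baseline
    weight. The package builds sparse excitatory/inhibitory topologies,
    encodes images as Poisson spike trains, trains networks on visual
    word sequences, generates character sequences from top-2 population
    activity without a readout layer, and provides diagnostics: eigenvalue
    spectra of the recurrent weight matrix, PCA trajectories of population
    activity, weight-structure scores, and noise-robustness sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
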