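Package: engramnet
Title: Homeostatic Structural Plasticity and Memory Engram Formation in
    Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spatial networks of Izhikevich spiking neurons whose
    connectivity is shaped entirely by homeostatic structural plasticity:
    each neuron grows and prunes axonal and dendritic synaptic elements so
    that its intracellular calcium concentration, a leaky integrator of its
    own spikes, holds a target set-point. Synapses form between vacant
    elements with a Gaussian distance-dependent probability, sampled either
    exactly or through a Barnes-Hut octree approximation. The package
    implements conditioned-learning stimulation protocols that form multiple
    non-interfering memory engrams, pattern-completion and lesion
    experiments, a 3-sigma readout-classification analysis battery with
    ensemble connectivity matrices, and an analytic signal-to-noise model of
    memory capacity under engram overwriting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
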