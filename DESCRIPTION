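Package: bumpcode
Title: Bump Population Codes and Gradient-Free Reinforce-Type Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation toolkit for population codes with rectangular tuning
    curves ("bump" activations) on neural grids, probabilistic synapses, and an
    abstract continuous-attractor readout. Implements gradient-free,
    reinforce-type learning algorithms for low-dimensional Lipschitz mappings:
    counter-based static and phase-halving dynamic algorithms amenable to
    sample-complexity analysis, simulation algorithms with per-neuron running
    error thresholds, immediate and inactivity-driven synaptic pruning,
    consolidation and adaptive tuning-curve width, and a k-step
    temporal-difference reinforcement-learning variant with a tabular value
    function and clipped synaptic-probability updates. Ships closed-form
    benchmark tasks (identity, sinus, second-order polynomial, ball throwing,
    two-joint robotic arm) and episodic control environments (continuous
    mountain car, cart-pole), plus error-estimation, learning-curve and
    sample-efficiency metrics with seeded, reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
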