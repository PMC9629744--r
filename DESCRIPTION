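Package: glifnet
Title: Laminar Spiking Network Models with Surrogate-Gradient Training and
    Neural-Coding Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale generalized leaky integrate-and-fire (GLIF_3) network
    models of a laminar cortical patch: distance-dependent synthetic
    connectomes obeying Dale's law, discrete-time simulation with after-spike
    currents, alpha-function synapses with conduction delays and a
    two-timescale heavy-tailed noise model, an LGN-style spatiotemporal filter
    front end, generators for five visual tasks, backpropagation-through-time
    training with a Gaussian pseudo-derivative under biological constraints,
    and the population-coding analyses (cross-validated PCA eigenspectra with
    power-law fits, discriminability index d-prime with PLS reduction and
    noise-covariance geometry, subsampling-robust branching-ratio estimation,
    Fano factors) used to characterize such models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    png,
    minpack.lm,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
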