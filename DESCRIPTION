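Package: memrec
Title: Bayesian Reconstruction of Memory Patterns from Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the activity patterns stored in a recurrent
    attractor network from its observed synaptic connectivity matrix. The
    connectivity is modelled as a rectified, noisy Hebbian weight matrix
    (a low-rank spiked matrix passed through a thresholded Gaussian output
    channel), and the patterns are inferred by an approximate message
    passing algorithm for low-rank matrix factorisation (Low-RAMP) with
    matched priors. Includes the scalar state-evolution analysis of the
    algorithm (critical noise levels, phase diagrams, hard-phase
    detection), spectral (PCA) baselines on the raw connectivity and on
    the Fisher score matrix, a generative model for synthetic instances,
    and scripted capacity experiments measuring how many patterns can be
    recovered at a given network size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    pracma,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
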