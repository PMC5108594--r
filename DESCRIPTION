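Package: divsenc
Title: Divisive Suppression Encoding Models for Retinal Ganglion Cell Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits and simulates nonlinear cascade models of retinal ganglion
    cell responses to temporal contrast stimuli. Implements the divisive
    suppression (DivS) model, in which an excitatory linear-nonlinear unit is
    multiplied by a suppressive unit whose gain is bounded between zero and
    one, together with its additive (AddS) and nonparametric two-dimensional
    controls, a three-state linear-nonlinear-kinetic (LNK) synaptic depression
    model, and point-process spiking extensions with spike-history
    (refractory) terms. Also provides response-weighted covariance analysis,
    coherence and noise-corrected predictive-power metrics, contrast
    adaptation LN analysis, spike-event precision statistics, seeded stimulus
    generators reproducing contrast-switching and spot-annulus protocols, and
    ground-truth generators for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
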