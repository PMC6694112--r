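Package: bnpfcs
Title: Bayesian Non-Parametric Analysis of Confocal Photon-Count Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule fluorescence confocal microscopy time
    traces. Provides a forward simulator of freely diffusing fluorophores
    emitting Poisson-distributed photon counts through a confocal point-spread
    function, and a Markov chain Monte Carlo engine that infers, from a single
    short binned photon-count trace, the diffusion coefficient, molecular
    brightness, background emission rate, the unknown number of contributing
    molecules (via a Beta-Bernoulli load prior) and their latent trajectories.
    A classical autocorrelation-based FCS baseline (multi-tau correlator plus
    nonlinear model fit) is included for data-efficiency comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
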