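Package: spikefit
Title: Maximum-Likelihood Fitting of Integrate-and-Fire Neuron and
    Microcircuit Models to Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistically principled estimation of mechanistic spiking-neuron
    models from single-trial spike trains. Likelihoods for leaky
    integrate-and-fire neurons driven by Gaussian white noise are computed
    analytically by solving the Fokker-Planck first-passage-time problem with
    an exponentially fitted finite-volume scheme, and maximized to infer
    hidden background-input statistics (mean and noise amplitude), weak input
    perturbations triggered at known times, spike-frequency adaptation
    parameters, and pairwise synaptic coupling strengths and delays in
    subsampled networks. Includes a linear-nonlinear cascade spike-rate
    reduction with an inhomogeneous-Poisson likelihood, Fisher-information /
    Cramer-Rao bounds, AIC model comparison, cross-correlogram baselines with
    jitter surrogates, and ground-truth simulators for all supported
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
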