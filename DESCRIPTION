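Package: waveHMM
Title: Wavelet-Compressed Inference for Gaussian Hidden Markov Models
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact and wavelet-compressed implementations of the three
    classical hidden Markov model algorithms (likelihood evaluation,
    Viterbi decoding, Baum-Welch training) for models with univariate
    Gaussian emissions. Observation sequences that are approximately
    piecewise constant with homoscedastic noise -- for example depth-of-
    coverage or array intensity signals used in copy-number segmentation --
    are compressed with a Haar wavelet lifting transform and the universal
    shrinkage threshold into blocks of sufficient statistics; the dynamic
    programming recursions then run over blocks instead of individual
    observations, which accelerates computation and Baum-Welch convergence
    with negligible effect on the computed log-probabilities. Includes a
    simulation and benchmarking harness that quantifies the approximation
    error and the convergence gains of compression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
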