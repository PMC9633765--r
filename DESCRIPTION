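Package: painlearn
Title: Bayesian Observer Models of Statistical Pain-Sequence Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how observers learn the temporal statistics
    of binary (low/high intensity) stimulus sequences. Generates volatile
    Markov sequences in which the transition matrix is occasionally
    resampled, runs six trial-by-trial observer models (a random baseline,
    a Rescorla-Wagner delta rule, leaky Beta-Bernoulli frequency and
    transition learners, and change-point-aware Bayesian learners
    implemented by grid-approximated hidden Markov model filtering), fits
    each model to probe-trial probability ratings by BIC-scored regression
    with multi-start optimisation, compares models with fixed-effects
    averaged BIC and random-effects Bayesian model selection (model
    frequencies, exceedance and protected exceedance probabilities), and
    exports trial-wise posterior mean, posterior SD and Kullback-Leibler
    update series as BIDS-style parametric-modulator event tables for
    first-level fMRI analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
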