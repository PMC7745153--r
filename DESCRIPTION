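Package: cudn
Title: Control of Uncertainty-Induced Decision Noise Under Blame Expectation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of a probabilistic reversal
    learning task in which wrong choices are probabilistically punished by
    social blame. Implements the CUDN (control of uncertainty-induced decision
    noise) model family: a three-level binary hierarchical Gaussian filter
    tracking cue-outcome contingencies, a Rescorla-Wagner learner tracking the
    conditional blame probability, and a softmax response model whose inverse
    temperature is modulated by estimation uncertainty and blame belief.
    Provides per-subject MAP fitting with Laplace-approximate model evidence,
    random-effects Bayesian model selection with protected exceedance
    probabilities, an ideal Bayesian observer benchmark, a synthetic cohort
    generator, and the behavioural statistics pipeline (block contrasts,
    reversal-locked learning curves, parameter-performance correlations, and a
    mood analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
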