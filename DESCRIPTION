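Package: establishr
Title: Predicting the Establishment of Introduced Species Under
    Demographic Stochasticity and Parameter Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how demographic stochasticity and
    imperfect knowledge of demographic parameters limit our ability to
    predict whether an introduced species will establish in a resident
    community. Implements exact (Gillespie) simulation of the stochastic
    logistic birth-death process for an invader competing with a resident
    community, a diffusion-approximation likelihood for discretely
    sampled, imperfectly observed abundance time series, Metropolis-
    Hastings posterior sampling of the resident-to-invader interaction
    strength under graded prior knowledge of the single-species
    parameters, and the predictability, predictive-ability, precision and
    accuracy metrics that summarise the limits of prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
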