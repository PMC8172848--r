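Package: ednafp
Title: Two-Stage Occupancy Models for Environmental DNA Surveys with
    False Positives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian multi-scale site-occupancy modelling for qPCR-based
    environmental DNA (eDNA) surveys in which detection error - both false
    negative and false positive - can arise at two stages: field sample
    collection and laboratory qPCR analysis. Provides the exact marginal
    likelihood of the two-stage model, Gibbs/Metropolis MCMC fitting with
    latent-state data augmentation (with optional site covariates on all
    probabilities via logistic links), a constrained variant that assumes
    no false positive error, a calibrated simulator of eDNA detection
    data, and a survey-design study engine that sweeps the number of
    sites, field samples and qPCR replicates to map bias and credible
    interval width. Includes derived quantities used to interpret eDNA
    surveys: per-site occupancy posteriors, the conditional probability
    of species absence given a number of amplifying qPCR replicates, and
    naive threshold-based occupancy rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
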