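Package: piheal
Title: Hierarchical Bayesian Prediction of Pressure-Injury Healing Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models changes in the DESIGN-R 2020 pressure-injury severity score
    between home-care nursing assessments with a hierarchical Bayesian
    regression whose per-lesion coefficient vectors follow a multivariate
    normal population distribution. Provides the DESIGN-R 2020 scoring and
    large/small dummy coding, a longitudinal synthetic cohort generator,
    posterior sampling by the No-U-Turn sampler with Gelman-Rubin diagnostics,
    Warp-III bridge-sampling marginal likelihoods and posterior model
    probabilities, the marginal-likelihood predictor-selection procedure,
    posterior predictive intervals with coverage-probability validation (the
    fail-safe signal for expert consultation), and vignette-based expert
    agreement and improvement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
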