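Package: dhmeta
Title: Frequentist Estimation of the Daniels-Hughes Surrogate Endpoint Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level surrogate endpoint evaluation with the Daniels-Hughes
    bivariate meta-analysis model. Provides numerical maximum likelihood
    estimation with estimating-equation certification of convergence, a
    bias-adjusted estimator of the between-study variance that corrects the
    incidental-parameters (Neyman-Scott type) downward bias caused by one
    nuisance surrogate-effect parameter per study, a reference Bayesian
    analysis by Metropolis-within-Gibbs sampling, a simulation engine for
    bias and coverage studies, and delimited-text input/output for
    study-level effect estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
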