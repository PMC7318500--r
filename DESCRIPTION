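Package: lcmroc
Title: Bayesian Latent Class Estimation of Diagnostic Accuracy Without a
    Gold Standard
Version: 0.1.0
Authors@R:
    person("lcmroc", "maintainers", email = "lcmroc@example.org",
           role = c("aut", "cre"))
Description: Estimates sensitivity, specificity and the area under the ROC
    curve of continuous diagnostic markers when no gold-standard reference
    test is available, using Bayesian two-class latent class models fitted
    by Markov chain Monte Carlo.  Supports the single-marker binormal model
    (Gibbs sampling), a covariate-adjusted multivariate-normal model with a
    logistic disease-prevalence submodel (Metropolis-within-Gibbs), optimal
    linear marker combinations with covariate-adjusted combined ROC curves,
    posterior summaries and convergence diagnostics (Geweke, batch-means
    Monte Carlo error, autocorrelation), and a synthetic cohort generator
    emulating a gestational-diabetes screening study for fully reproducible
    end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda,
    yaml,
    optparse
Config/testthat/edition: 3
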