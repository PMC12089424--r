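Package: cogvarme
Title: Variance Explained in Cognition Accounting for Measurement Error
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the proportion of variance in cognitive
    functioning explained by brain biomarkers while accounting for
    individually varying outcome measurement error. Provides item response
    theory (graded response model) simulation and expected a posteriori
    scoring with per-person standard errors of measurement, a synthetic
    three-group (cognitively normal / MCI / AD) cohort generator with
    correlated biomarkers, Bayesian normal linear models with and without a
    latent true-cognition measurement-error term (Gibbs sampling with
    split-chain R-hat diagnostics), Bayesian R-squared variance
    decomposition with credible intervals, and a pipeline orchestrating
    per-biomarker, all-biomarker and diagnosis-stratified analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
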