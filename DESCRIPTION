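Package: hazescore
Title: Hazardous Gaming and Internet Gaming Disorder Screening from the
    CSAS Parent Report
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the parent-report Video Game Dependency Scale (CSAS-PR)
    for Internet Gaming Disorder (IGD) and an adapted Hazardous Gaming (HG)
    classification in children, and analyses the psychometric properties of
    the 11-variable HG scale: item difficulty and discrimination, pairwise
    inter-item correlations, standardized Cronbach's alpha, exploratory
    maximum-likelihood factor analysis with oblimin rotation, multi-criterion
    factor retention (parallel analysis, empirical Kaiser criterion,
    comparison data, sequential likelihood-ratio tests, BIC, RMSEA, scree),
    bootstrap confidence intervals for loadings, higher-order factor
    extraction, prevalence estimates with Wald intervals, cross-construct
    overlap and Cohen's kappa. A synthetic-cohort generator with a
    two-factor, higher-order latent structure and calibrated ordinal
    marginals makes the whole pipeline testable without access to raw
    questionnaire data.
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
    e1071,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
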