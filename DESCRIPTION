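Package: popmediate
Title: Mediation Analysis of Race Differences in Telomere Length Through
    Correlated Pollutant Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how much of the Black/White difference in
    leukocyte telomere length is transmitted through exposure to correlated
    persistent organic pollutants (PCBs, dioxins, furans), in the style of the
    NHANES 1999-2002 analyses. Implements survey-weighted single-mediator
    product-of-coefficients mediation with Sobel inference and
    Benjamini-Hochberg correction, sequential censored-likelihood multiple
    imputation of below-detection-limit concentrations, multivariate
    (unpenalized and ridge-penalized) mediation with bootstrap inference,
    summary-score mediators (principal components, principal direction of
    mediation, toxic equivalency), E-value sensitivity analysis, and a
    synthetic-cohort generator with known ground-truth effects for validating
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
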