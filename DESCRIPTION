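Package: ovaudit
Title: Random-Effects Bivariate Probit Analysis of Ovary-Visualisation Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of expert-review audits of sonographer-reported
    visualisation of paired organs (left and right ovary), as used to audit
    transvaginal-sonography quality in ovarian cancer screening. Fits a
    bivariate probit model with correlated scan-level random intercepts by
    maximum likelihood (tensor-product Gauss-Hermite quadrature with an
    optional adaptive rule), and provides Wald inference, population-averaged
    marginal and joint predictions with delta-method standard errors,
    intraclass correlation coefficients, tetrachoric correlations, empirical
    Bayes random-effect means, a synthetic audit-data generator matching the
    audit design, and a reproducible analysis pipeline with a parameter
    recovery study.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    haven,
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
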