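Package: rrbmnlfa
Title: Measurement Invariance and Growth Modelling for Early Repetitive Behaviors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Moderated nonlinear factor analysis (MNLFA) for binary
    questionnaire items, with an automated longitudinal
    measurement-invariance workflow and mixed-effects growth-curve
    analysis of the resulting factor scores. Provides marginal
    maximum-likelihood estimation by Gauss-Hermite quadrature with
    covariate moderation of factor mean, factor variance, item
    intercepts and item loadings; item-wise differential item
    functioning (DIF) scans with trimming and Benjamini-Hochberg
    correction; expected-a-posteriori factor scoring; a two-factor
    configural structure check; a synthetic accelerated-longitudinal
    data generator with known ground truth; and growth-model taxonomy
    search with likelihood-ratio tests and small-sample AIC.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
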