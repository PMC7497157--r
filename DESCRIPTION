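Package: osteosex
Title: Probabilistic Sex Estimation from Skeletal Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating probabilistic sex estimation
    models from continuous skeletal measurements. Fits two-group linear
    discriminant functions on a standardized score axis with plug-in posterior
    probabilities, and binomial logistic regression by maximum likelihood.
    Evaluates models by leave-one-out cross-validation at configurable
    decision probabilities, the Brier-based B index and the logarithmic Q
    index, and a sample-size subsampling experiment. Implements the bootstrap
    "PMark" procedure, which converts posterior-probability levels (e.g. 0.80,
    0.90, 0.95) into additional discriminant-score cutoff points so that
    discriminant scores can be reported on the standard five-category scale
    (female, probable female, indeterminate, probable male, male) instead of a
    dichotomy. Includes assumption diagnostics (variance inflation factors,
    Box's M, Mahalanobis outliers, logit-linearity) and a seeded synthetic
    reference-sample generator for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
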