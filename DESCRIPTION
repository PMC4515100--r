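Package: miperform
Title: Prediction Model Performance with Multiply Imputed Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives generalized linear prediction models on multiply imputed
    covariate data and assesses their performance. Implements the full taxonomy
    of imputation-specific and pooled predictions (P1-P9), the pooled-performance
    and pooled-prediction evaluation strategies, ideal versus pragmatic
    performance estimators (a second imputation excluding the outcome, and
    partial prediction models fitted per observed-covariate pattern), chained
    equations imputation with predictive mean matching, Rubin's rules pooling,
    MCAR and staged MAR missingness mechanisms, a synthetic trial-like data
    generator, and a Monte Carlo scenario engine with paired replicate storage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
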