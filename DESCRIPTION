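Package: tAgeClock
Title: Transcriptomic Age Prediction with a Poisson Maximum-Likelihood Clock
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds transcriptomic aging clocks from bulk RNA-seq count
    matrices. Gene counts are normalized to compositional frequencies, each
    gene's frequency-versus-age trend is smoothed with locally weighted
    linear regression (LOWESS), and genes are ranked by the absolute Spearman
    correlation of frequency with age. The top-ranked genes form a reference
    of expected frequencies over a discrete age grid; a sample's
    transcriptomic age is the grid age maximizing the summed Poisson
    log-likelihood of its observed counts. Includes leave-one-out
    cross-validation, residual-bias diagnostics, an Elastic-Net regression
    baseline, and a synthetic-cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
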