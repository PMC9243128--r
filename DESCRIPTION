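Package: glycoblock
Title: Multi-Block Integration of Plasma N-Glycan Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of total plasma N-glycome UPLC peak tables
    for two-group discrimination: empirical-Bayes batch correction, median
    quotient normalisation, rank transformation, declarative derived-trait
    computation, univariate screening with Benjamini-Hochberg FDR control,
    Ward hierarchical cluster signatures, a from-scratch sparse generalized
    canonical correlation (sGCCA/DIABLO) discriminant core with
    cross-validation and AUC, and relevance-network inference. Ships a
    logistic-normal compositional glycome simulator with plate-wise batch
    artefacts and planted group effects so the whole chain is testable
    without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    mixOmics
Config/testthat/edition: 3
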