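Package: agingaccel
Title: Pan-Cancer DNA Methylation Aging Acceleration Analysis
Version: 0.1.0
Authors@R:
    person("Agingaccel", "Developers", email = "agingaccel@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for pan-cancer aging-acceleration
    analysis from paired tumor/adjacent-normal multi-omics profiles: a
    multi-tissue DNA-methylation aging-score predictor (Kruskal-Wallis
    marker screen, leave-one-tissue-out cross-validated linear support
    vector regression), LASSO selection of aging-acceleration-associated
    mutation and expression modules, an information-theoretic (mRMR) eQTL
    module finder with leave-one-out module sizing, hypergeometric gene-set
    enrichment, and a Kolmogorov-Smirnov cross-cancer similarity network.
    Ships a paired multi-omics cohort simulator with known ground truth so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
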