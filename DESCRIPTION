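Package: grcca
Title: Group-Regularized Canonical Correlation Analysis for Transcriptomic Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links bulk RNA-seq expression to diagnosis and exposure covariates with
    group-regularized canonical correlation analysis (GRCCA), using co-expression
    modules as the grouping structure. Provides the full surrounding pipeline:
    count filtering and coefficient-of-variation filtering, size-factor
    normalization and covariate residualization, principal-component covariate
    screening, multiple correspondence analysis of categorical toxicology
    exposures, simplified weighted co-expression module detection
    (soft-threshold adjacency, topological overlap, static tree cut),
    permutation model selection over the retained-variance fraction, bootstrap
    weight Z-scores, structure correlations with dual significance criteria, a
    per-feature linear-model differential expression arm, preranked gene set
    enrichment, hypergeometric overlap tests, and decile developmental
    trajectory summaries. A negative-binomial simulator with planted
    co-expression modules and diagnosis effects provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    DESeq2,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
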