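Package: mamcross
Title: Cross-Species Mammary Tumor Subtyping and Homology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised discovery of mammary tumor subtypes from bulk
    RNA-seq expression (non-negative matrix factorization with cophenetic
    rank selection and consensus over gene subsets), PAM50-style
    nearest-centroid classification tolerant of partial gene panels, a
    resampled cross-species co-clustering test of subtype homology with
    Mahalanobis distance statistics, Boruta-style all-relevant feature-gene
    selection on top of pairwise differential expression pools, and the
    downstream expression statistics used in comparative oncology studies
    (negative-binomial Wald differential expression, single-sample gene set
    enrichment scores, dual Pearson/Spearman correlation screens,
    receptor-status calls from FPKM thresholds, and subgroup crosstabs).
    Includes a seeded two-species cohort simulator with known ground truth
    so the whole pipeline is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mclust,
    ranger,
    stats,
    sva,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
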