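Package: gliastate
Title: Reactive-Astrocyte State Scoring and Subgroup Discovery for Glioblastoma Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for bulk expression profiles of
    tumor-associated astrocytes: median-of-ratios normalization with a
    simplified negative-binomial Wald test for differential expression,
    fold-change rank-shift comparison between experimental contexts,
    unsupervised subgroup discovery by partitioning-around-medoids with
    silhouette-based model selection and core-sample filtering, marker gene
    identification by nearest shrunken centroids or per-gene logistic
    models, permutation-based pre-ranked gene-set enrichment with FDR
    control, signature-based scoring of astrocyte reactive states (A1/A2,
    fetal/adult) onto a two-dimensional differentiation-reactivity map, and
    flow-cytometry post-processing (arcsinh transform, gating, per-cell
    over-dispersion, embedding, cluster-by-condition summaries). A
    synthetic-data generator with planted ground truth supports testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rtsne,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
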