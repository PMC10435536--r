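Package: crossOncoSig
Title: Prognostic Gene-Signature Discovery and Cross-Species Transfer for
    Osteosarcoma Transcriptomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovery and cross-cohort transfer of prognostic gene
    expression signatures in bulk RNA-seq cohorts, modeled on comparative
    canine/human osteosarcoma studies. Implements two companion
    workflows: (a) application of an existing gene signature by
    outcome-blind K-means clustering with silhouette model selection,
    followed by Kaplan-Meier / log-rank survival comparison, two-class
    GSEA and moderated-t differential expression; and (b) de novo
    signature discovery via single-sample GSEA (ssGSEA) scoring of
    hallmark-style gene sets, clustering of the enrichment profile,
    voom-style differential expression, and seeded consensus bi-clustering
    with the Iterative Signature Algorithm (ISA). Includes expression /
    gene-set / clinical readers (TSV, GCT 1.2, GMT), edgeR-based low-count
    filtering and TMM normalization, quantile normalization, survival
    statistics (Kaplan-Meier, log-rank, univariate Cox, chi-square
    goodness of fit, Mann-Whitney U), and a synthetic-cohort generator
    with planted prognostic modules, planted bi-clusters, negative
    binomial count noise, and cluster-linked survival for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    limma,
    survival,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, Transcriptomics, Clustering, Survival,
    DifferentialExpression, GeneSetEnrichment
RoxygenNote: 7.3.3
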