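Package: OAsubtypes
Title: Molecular Subtype Discovery and Tissue Crosstalk Analysis for
    Osteoarthritis Joint Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovery and characterization of molecular subtypes of knee
    osteoarthritis from multi-tissue bulk RNA-seq count matrices. Provides
    quality control and CPM normalization with depth, control-variance and
    minimum-expression filters; SC3-style consensus clustering of the
    cartilage transcriptome with silhouette-driven selection of the number
    of highly variable genes and clusters; AUROC-ranked marker-gene
    detection and pairwise differential expression; directed ligand-receptor
    tissue-crosstalk scoring across cartilage, synovium and subchondral
    bone with an occurrence-ratio statistic and hypergeometric enrichment;
    Cochran-Armitage trend tests linking subtypes to ordered clinical
    scores; and random-forest transfer of subtype labels to external
    cohorts. A synthetic multi-tissue cohort generator with known ground
    truth supports end-to-end validation without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Clustering, Classification,
    RNASeq
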