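Package: egrnet
Title: Enhancer Gene-Regulatory-Network Inference from Paired Single-Cell Multiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed enhancer gene-regulatory networks (eGRNs) from paired
    single-cell RNA and ATAC count matrices: cell and cluster quality control,
    iterative-overlap consensus peak merging, latent Dirichlet allocation topic
    modelling of binarized accessibility with coherence-based model selection and
    topic-imputed accessibility, Wilcoxon differential accessible regions and a
    Poisson log-likelihood-ratio pseudo-bulk track contrast, recovery-curve motif
    enrichment (AUC/NES) with direct and extended TF cistromes, gradient-boosted
    region-to-gene and TF-to-gene importances with Spearman correlations inside a
    TSS-distance window, correlation-signed edge dichotomization, multi-rule edge
    pruning with GSEA leading-edge selection, per-cell AUCell activity scoring,
    pseudo-bulk quality filtering and regulon specificity scores. Ships a seeded
    synthetic multiome generator with planted TF-region-gene regulatory structure
    so every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    stats,
    utils,
    tools,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
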