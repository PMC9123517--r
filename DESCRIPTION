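Package: pvrsig
Title: Inverse-Signature Drug Repurposing and Single-Cell Phenotyping for
    Fibrotic Retinal Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for transcriptome-based drug repurposing in
    proliferative vitreoretinopathy (PVR) and related fibrotic membrane
    disease. Builds a ranked disease signature from bulk RNA-seq counts
    (internal differential-expression stand-in, TPM, DEG filtering,
    hypergeometric over-representation, Benjamini-Hochberg adjustment),
    retains interacting genes against a STRING-style network, filters a
    DrugBank-like catalog, and scores each candidate drug's downregulated
    gene set against the disease ranking with a weighted running-sum
    enrichment statistic calibrated by gene-set permutation (NES, FDR).
    Also provides ssGSEA-style cell-type enrichment with exact Mann-Whitney
    group comparison, and imaging-mass-cytometry single-cell phenotyping
    (percentile normalization, kNN/Jaccard graph community clustering,
    cluster profiles and composition, threshold gating). A synthetic-data
    module generates every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
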