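Package: ctcprofiler
Title: Single-Cell Transcriptome Profiling of Cerebrospinal-Fluid Circulating Tumor Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterizing circulating tumor cells in
    cerebrospinal fluid (CSF-CTCs) from Smart-seq2 single-cell RNA-seq count
    matrices: gene- and cell-level quality control, marker-panel cell typing,
    gene-set scoring (expression-matched-control module scores, single-sample
    rank enrichment, gene-set-variation-style scores, preranked GSEA with
    permutation FDR), cell-state classification (cell cycle, partial EMT,
    cancer-stem-cell markers, cancer-testis-antigen burden), intra- versus
    inter-patient heterogeneity via pairwise transcriptome correlations,
    two-group differential expression with Benjamini-Hochberg FDR and
    diagnostic panel selection, plus a negative-binomial-with-dropout
    simulator that emits ground-truth labels so every stage is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
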