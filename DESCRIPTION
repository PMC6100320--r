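Package: qpathdiff
Title: Quantitative Pathway Divergence Analysis for Multi-Treatment
    Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies and tests how biological pathways respond
    differently to alternative treatments from bulk expression data.
    Calls differentially expressed genes per treatment-versus-reference
    contrast with fold-change and ANOVA p-value thresholds, scores
    pathway enrichment by the hypergeometric test, assembles per-treatment
    gene-by-pathway fold-change profile tables, co-projects the tables
    into a single common space by multiple co-inertia analysis (MCOA),
    and assigns each pathway a between-treatment divergence score with a
    value-permutation null, Benjamini-Hochberg corrected. Includes a
    synthetic-data generator with planted pathway effects and known
    divergence ground truth, and a single-command pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Pathways, DifferentialExpression,
    DimensionReduction, Microarray
RoxygenNote: 7.3.3
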