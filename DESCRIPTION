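Package: cgsc
Title: Identification of Core Glioma Stem Cells and Their Immune-Evasive Phenotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies embryonic-like "core" glioma stem cells (c-GSCs) in
    single-cell expression data by an upper-quartile triple-marker rule over
    OCT4, SOX2 and NANOG, and characterizes their immune-evasive phenotype by
    integrating bulk RNA-seq differential expression, gene-set
    over-representation with Cohen's kappa pathway agreement, and EPIC-style
    DNA-methylation analysis (beta-value standardization, differential
    methylation, promoter-window aggregation, consensus transcription-factor
    binding-site intersection and distance metaprofiles). Ships a synthetic
    cohort generator with planted ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    tools,
    Matrix,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
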