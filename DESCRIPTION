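Package: oomt
Title: Joint Single-Cell Methylome and Transcriptome Analysis of Oocyte Ageing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of single-cell bisulfite sequencing
    (scBS-seq) and single-cell RNA sequencing (scRNA-seq) data from paired
    profiling of the same cells (scM&T-seq), developed around germinal-vesicle
    oocytes from reproductively young and aged females. Implements quality
    control of sparse single-cell methylomes, quantification of CpG and
    non-CpG methylation over the oocyte's bimodal hyper-/hypo-methylated
    domain landscape, a randomised pseudobulk consensus caller for
    age-associated differentially methylated regions based on weighted
    logistic regression with per-combination false discovery rate control,
    transcriptional classification of nucleolar chromatin state, differential
    mean and variability testing, detection of young-like subpopulations, and
    per-cell coupling of gene-body methylation with expression. A synthetic
    data generator with planted ground truth emulates the statistical
    structure of such datasets so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
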