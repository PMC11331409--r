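Package: adarscope
Title: Differential A-to-I Editing, Translatome and Small-RNA Analysis for ADAR1 Knockout Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational analyses used to
    characterise an ADAR1-knockout hepatocyte cell line: differential A-to-G
    editing-site calling between replicate groups with a beta-binomial
    likelihood-ratio score and a filter cascade, transcript-region, repeat and
    codon-consequence annotation of edited positions, an Alu editing index,
    negative-binomial Wald tests including the cell-line by polysome-fraction
    interaction that classifies mRNAs into retarded or enhanced polysome
    loading, logistic membership-odds enrichment, small-RNA class and
    read-length summaries, and image-based cell-area quantification by seeded
    region growing. All stages run on seeded synthetic data with recorded
    ground truth, so every result is reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
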