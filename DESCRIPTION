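Package: errbs
Title: Base-Pair Resolution DNA Methylation Analysis for Enhanced RRBS
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of enhanced reduced representation bisulfite sequencing
    (ERRBS) methylomes at single-CpG resolution: reading and writing
    bismark-style methylation call tables, in-silico MspI digestion with
    fragment size selection and coverage accounting, strand-merged methylation
    calling with quality and coverage filters, CpG island/shore and
    gene-feature annotation, per-CpG differential methylation testing by
    binomial logistic-regression likelihood-ratio tests with SLIM false
    discovery rate control, peak and repeat enrichment statistics, and
    integration of promoter methylation with gene expression. Includes a
    synthetic methylome generator that emulates two tumor subtypes with
    opposed differential methylation architectures against a normal control,
    with recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
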