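Package: updmr
Title: Differentially Methylated Region Calling via the Uniform-Product Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from whole-genome
    bisulfite sequencing CpG count tables. Per-CpG differential methylation is
    tested with Fisher's exact test (two samples) or binomial logistic
    regression (one sample versus a pooled group); runs of five or more
    consecutive site p-values are combined with the Uniform Product (UP)
    joint-probability statistic, and candidate regions are filtered on percent
    methylation difference, length and inter-site gaps. Includes pairwise /
    multi-control intersection of DMR sets, one-to-many tissue-specific DMR
    calling across a methylome panel, rule-based annotation against chromatin
    state segmentations and gene models, and a synthetic methylome generator
    with planted DMRs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
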