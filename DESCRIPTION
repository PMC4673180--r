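Package: gbmirnome
Title: Small-RNA isomiR, Editing and Expression Profiling of Glioblastoma Tumor and Peritumor Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a transcriptome and miRNome
    profiling workflow for paired glioblastoma tumor-center (C) and
    peritumor (P) tissue: isomiR detection and miRNA A-to-G editing
    quantification from small-RNA reads, trimmed-mean-of-M-values (TMM)
    normalization with counts-per-million filters, pooled two-proportion
    editing statistics with continuity correction, ReliefF feature ranking
    with leave-one-out merit averaging, single-sample gene-set enrichment
    (ssGSEA) subtype classification, CATG-anchored SAGE tag extraction and
    counting, fold-change signature selection against a healthy control,
    and seed-site target-shift analysis for edited microRNAs. A bundled
    synthetic-data generator with recorded ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
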