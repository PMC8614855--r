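Package: lncwhiten
Title: De Novo lncRNA Identification and Characterization During Brown
    Adipose Tissue Whitening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a de novo long non-coding RNA
    (lncRNA) discovery and characterization pipeline for time-course bulk
    RNA-seq, motivated by aging-related whitening of brown adipose tissue.
    Provides structural and expression filtering of assembled transcripts,
    strand-aware positional classification into lincRNA, antisense,
    intronic and sense-overlapping categories, a four-predictor
    coding-potential consensus, cis-target assignment (host gene or 100-kb
    flank), lncRNA-target Pearson correlation screening, transcriptional
    complexity (top-k expression share) profiling, a simplified
    negative-binomial Wald test with Benjamini-Hochberg FDR for
    differential expression, k-means expression-pattern clustering,
    hypergeometric pathway enrichment, and a fully self-contained
    synthetic-data generator with a ground-truth ledger.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
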