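Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete workflow for two-library digital gene expression
    (DGE/SAGE-style) tag profiling: construction of a virtual reference tag
    library by in-silico NlaIII/MmeI digestion of prioritised transcript
    databases, raw-tag filtering with a conservation ledger, saturation and
    copy-number analyses, one-mismatch tag-to-gene mapping with a
    mitochondrial and nuclear genome cascade, tags-per-million
    normalisation, the Audic-Claverie exact test with Benjamini-Hochberg
    false discovery rate control for two-library differential expression,
    hypergeometric GO/pathway enrichment with Bonferroni correction, and
    2^-delta-delta-Ct relative quantification for qPCR validation. A
    synthetic-data module generates fully specified transcriptomes, genomes,
    tag libraries and annotation tables with a truth ledger so that every
    stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
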