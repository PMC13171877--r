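Package: pcfidelity
Title: Multi-Omics Fidelity Assessment of Prostate Cancer Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates how faithfully prostate cancer cell lines and
    organoids model metastatic disease across somatic mutations, copy
    number, bulk and single-cell transcriptomes, and chromatin
    accessibility. Implements mutation-panel construction (site-wise
    Fisher screening and high-frequency selection), hotspot cataloguing,
    gap-based hypermutation classification with mismatch-repair
    validation, gene-level differential copy number, highly-variable-gene
    Spearman correlation ranking of models against patient references,
    ssGSEA-based ARPC/NEPC/MSPC subtype assignment, lineage assignment
    against normal epithelial pseudo-bulks, variable-peak ATAC similarity
    with paired signed-rank comparisons, and a seeded synthetic
    multi-omics cohort generator with planted ground truth for recovery
    benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
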