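Package: serbptools
Title: RNA-Binding Protein Motif Discovery, Promoter Methylation Calling
    and Quantitative Models for an RBP Regulatory Study
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational arms of an RNA-binding-protein
    (RBP) regulatory study in glioblastoma: design and audit of an
    RNAcompete-style oligonucleotide pool built on an order-11 de Bruijn
    sequence with combinatorial k-mer coverage guarantees; 7-mer Z-scoring
    of probe intensities and position-frequency-matrix motif assembly; a
    permutation test for motif enrichment in 3'UTRs of RIP-Seq targets;
    a promoter H3K27me3 caller over +/- 3 kb TSS windows with a
    multi-sample consensus rule; differential-expression threshold filters
    and gene-set integration; a one-site fluorescence-polarization binding
    model; probabilistic quotient normalization, QC coefficient-of-variation
    filtering and volcano selection for metabolomics; and a composite
    immunohistochemistry scoring scheme. Seeded synthetic-data generators
    with recorded ground truth make every stage testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    IRanges,
    jsonlite,
    minpack.lm,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
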