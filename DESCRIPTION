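Package: srnamir
Title: Small RNA Sequencing Analysis of Known and Novel miRNAs Between Two Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from raw two-condition small-RNA sequencing
    reads to differentially expressed known and novel miRNAs and their
    predicted targets. Implements adaptor/junk read cleaning and tag
    collapsing, perfect-match genome mapping with a priority annotation
    cascade, perfect-match known miRNA calling, hairpin-criteria novel miRNA
    prediction (minimum free energy plus miRNA/miRNA-star duplex geometry),
    TPM normalization, the exact two-library count test with fold-change and
    p-value cut-offs, complementarity penalty scoring of target sites, and
    ddCt qPCR concordance. A synthetic-data module generates two-condition
    libraries with planted miRNAs and ground truth so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
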