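Package: circvalid
Title: In Silico Validation of Circular RNAs from a Gene Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a gene locus with linear splice variants and predicted
    circular RNAs, and re-creates the computational reasoning used to validate
    circRNAs experimentally: divergent/convergent in silico PCR with
    rolling-circle concatemer templates, back-splice-junction (BSJ) specific
    primer and antisense-oligonucleotide design, exon-path decomposition and
    classification of cloned amplicon sequences, local-alignment screening of
    flanking introns for inverse-complementary repeats, RNase R and
    RNase H + asON topology tests, and pooled lg10(fold-change) marker
    arithmetic for expression tables. Ships a synthetic TRAM1-like fixture
    locus and seeded generators for loci, clone libraries and expression
    tables so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
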