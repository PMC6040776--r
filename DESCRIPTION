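Package: mirdevnet
Title: Comparative Developmental miRNAome Analysis from Small RNA Tag Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparative small RNA sequencing studies of
    developing tissue across two genotypes and a short time course. Implements
    collapsed-tag preprocessing, exact genome mapping with a single-annotation
    priority rule (rRNA-class > known miRNA > repeat > exon > intron), hairpin-based
    novel miRNA candidate calling by base-pair-maximization folding, tags-per-million
    normalization with a zero revision and a high-expression filter, the
    Audic-Claverie exact test for between-library differential expression,
    model-profile (STEM-style) short time-series clustering with exact permutation
    significance, principal component and hierarchical cluster analysis of
    libraries, and construction of negative-correlation miRNA-mRNA interaction
    networks with hub extraction and binomial-test term overrepresentation.
    Ships a synthetic-data generator that plants known effects (breed-differential
    miRNAs, declining temporal trends, novel hairpins, regulatory target pairs)
    so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
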