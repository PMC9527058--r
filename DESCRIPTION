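Package: kenum
Title: Genome-Wide Enumeration of Single- and Multicopy CRISPR Target
    Sites with Fast Off-Target Counting
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Enumerates every k-mer target site matching a
    pattern-constrained motif (for example a 20-mer spacer followed by
    the SpCas9 NGG PAM) on both strands of a genome, computes genome-wide
    copy numbers by sorting compact binary-encoded site records, and
    evaluates off-target burden with a bit-array index of k-mer sequence
    space queried through bitwise AND/OR mask pairs. Multicopy spacers
    whose copies co-locate within a genomic window are called as clusters
    for live-cell genome imaging applications, and the resulting extended
    BED databases can be filtered, sorted and reduced to the best n
    guides per region of interest. Includes a synthetic-genome simulator
    with planted sites, clusters and controlled-distance neighbors so the
    whole pipeline is testable without reference genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
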