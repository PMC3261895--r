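Package: mappable
Title: Genome Mappability Tracks and Mappability-Aware Expression Normalization
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-position k-mer frequency and mappability of a
    reference genome allowing up to m substitutions, using both an exhaustive
    scan and a fast propagation-based approximation controlled by a threshold
    parameter t. Tracks are serialized to a compact pseudo-multi-FASTA format
    with one printable ASCII character per base, support indexed region
    retrieval, and export to BedGraph. Downstream utilities derive pileup
    mappability, paired-end mappability with read rescue, rescue-fraction
    sweeps over insert sizes, and mappability-corrected expression (RPKUM)
    over exon-union projected transcriptomes. A synthetic-genome module
    generates fixtures with planted repeat families of known copy number and
    divergence for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
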