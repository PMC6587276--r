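Package: pingpongr
Title: Ping-Pong piRNA Signatures and Transposon Insertion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Small-RNA analyses for transposable-element silencing studies in
    the Drosophila germline: loading and collapsing of 18-30 nt small-RNA
    libraries, gap-free k-mismatch read mapping to transposon consensus and
    genome references, ping-pong signature statistics (5'-overlap histogram,
    Z-score, ping-pong partners, 1U/10A nucleotide bias), RPM-normalized
    sense/antisense density profiles, piRNA-cluster composition of
    genome-unique mappers, and detection of non-reference transposon
    insertions (including inside repetitive piRNA clusters) from chimeric
    junction reads and discordant read pairs. Includes seeded simulators for
    piRNA libraries with configurable ping-pong structure and for paired-end
    genomic readsets around a planted insertion with target-site duplication,
    each with machine-readable truth records, so that every pipeline stage is
    verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
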