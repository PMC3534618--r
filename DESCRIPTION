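Package: readsqueeze
Title: Streaming Read Compression for Sequence Aligners
Version: 0.1.0
Authors@R:
    person("readsqueeze", "developers", email = "readsqueeze@example.org",
           role = c("aut", "cre"))
Description: Deduplicates redundant short sequencing reads on the fly,
    passes only unique sequences to a wrapped SAM-producing aligner, and
    reconstitutes full SAM output with correct multiplicities and strand
    orientations. Reads are stored as compact 2- or 3-bit-per-base packed
    objects keyed by MurmurHash2; reverse-complement canonicalization
    collapses strand duplicates in single-end data and order-swapped
    duplicates in forward-reverse paired data. Includes analytic runtime
    and memory predictors, a read-redundancy profiler (unique-read
    fraction versus subset size and 3' trim length), a deterministic
    built-in toy aligner for testing, and a synthetic library generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
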