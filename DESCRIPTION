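Package: hapfind
Title: Variant-Aware k-mer Index for Locating Patterns in Haplotype
    Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a searchable index over a collection of haploid genomes
    represented compactly as a reference genome (FASTA) plus a database of
    variants with phased genotypes (VCF). Answers exact and k-mismatch locate
    queries, reporting reference-anchored positions together with the exact
    set of haploid genomes that carry each match. The index enumerates every
    k-mer occurring on any variant path, stores it as a decoding recipe in
    four lexicographically sorted subarrays with lookup tables, compresses
    per-variant genotype bit-vectors through a chunk dictionary, and supports
    sparse (suffix-array-style sampled) storage with shifted-seed search as
    well as pigeonhole-partitioned approximate matching. Includes a synthetic
    collection/query generator and a naive-scan oracle for end-to-end
    verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
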