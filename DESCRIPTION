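Package: retrozyme
Title: Discovery and Annotation of Retrozymes in Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structure-based detection of hammerhead ribozymes (HHRs) in
    genomic DNA in their three circularly permuted topologies, assembly of
    tandem HHRs into retrozyme retroelements (direct-repeat LTR pair,
    target-site duplication, primer-binding-site and polypurine-tract
    junction boxes), extraction of the cleavage-to-cleavage monomer RNA,
    secondary-structure statistics by weighted base-pair maximization,
    consensus rendering with conservation thresholds, and a seeded
    synthetic-genome simulator with machine-readable ground truth for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
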