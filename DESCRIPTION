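Package: missmax
Title: Longest Common Substrings with Mismatches for Alignment-Free
    Sequence Comparison
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact and relaxed filtering algorithms that compute, for every
    suffix of a query sequence, the length of its longest common prefix
    with at most k mismatches against any position of a subject sequence.
    From this per-suffix vector the package derives the longest (k-mismatch
    longest common factor) and average (kACS) common substring statistics,
    ACS-style normalized distances, pairwise distance matrices in PHYLIP
    format and neighbor-joining trees for alignment-free phylogenetics.
    Includes a naive quadratic reference and a greedy (kmacs-style)
    baseline for validation and precision comparison, plus a synthetic
    uniform-random sequence generator and filtering-power benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    withr,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
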