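Package: rowlcs
Title: Row-Parallel Longest Common Subsequence for DNA Sequences
Version: 0.1.0
Authors@R:
    person("rowlcs", "developers", email = "rowlcs@example.org", role = c("aut", "cre"))
Description: Computes the length of the longest common subsequence (LCS) of two
    nucleotide (or arbitrary-alphabet) sequences with a family of dynamic
    programming algorithms: the classical prefix score table, a two-row
    space-optimized variant, and two row-wise-independent kernels driven by a
    precomputed last-occurrence table that removes within-row data dependencies
    so each score row can be evaluated in parallel under configurable
    work-sharing schedules (static, dynamic, guided). Includes a FASTA reader,
    a seeded random DNA generator with planted common subsequences for testing,
    a benchmark harness with relative and absolute speedup reporting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
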