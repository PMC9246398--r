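Package: swsystolic
Title: Smith-Waterman Alignment with Stored Traceback Directions and a
    Systolic-Array Simulator
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Local pairwise sequence alignment (Smith-Waterman, linear gap
    penalty) in which the forward dynamic-programming stage records, for
    every cell, a two-bit direction code alongside the score and tracks the
    running maximum, so that traceback reduces to walking a stored chain of
    directions from the maximum-score cell.  Includes a cycle-stepped
    simulator of a systolic processing-element array (one element per query
    symbol) that computes the matrix along anti-diagonal wavefronts and is
    verified cell-for-cell against the sequential aligner, GCUPS (giga cell
    updates per second) throughput accounting, FASTA input/output, a
    synthetic sequence generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
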