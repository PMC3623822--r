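Package: staligner
Title: Short-Read Alignment with an FM-Index, a Truncated Suffix-Trie
    Accelerator and Lower-Bound Pruning
Version: 0.1.0
Authors@R:
    person("Staligner", "Developers", email = "staligner@example.org",
           role = c("aut", "cre"))
Description: A desk-scale DNA short-read aligner built on backward search over
    the Burrows-Wheeler transform. Provides a sentinel-terminated FM-index
    (suffix array, bucketed Occ, sampled locate), a Suffix Tarray index (a
    frequency-truncated trie over the reversed reference caching suffix-array
    intervals on top of the FM-index), bounded inexact search with gap-open /
    free-gap-extension semantics, two per-prefix lower bounds on edit cost used
    to prune the search (single-mismatch segmentation and a tighter bound
    driven by an Aho-Corasick automaton of mined frequent two-edit patterns),
    a wgsim-style read simulator with truth-encoded names, TPR/PPV evaluation
    against simulation truth, SAM output, and a BWA-like command line
    interface (index, train, aln, simulate, evaluate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
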