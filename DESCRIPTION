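Package: under2
Title: Assembly-Free Comparison of Sequencing Read Sets with
    Variable-Length Underlying Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Alignment-free and assembly-free comparison of sets of
    unassembled sequencing reads.  Implements the Under2 dissimilarity
    built from variable-length irredundant and underlying common
    patterns weighted by first-order Markov expected occurrence counts,
    together with the fixed-k D2 family of comparator statistics (d2,
    d2*, d2S), a motif-implantation read simulator (common-motif,
    simple-multiple-motifs and full-multiple-motifs correlation models
    over i.i.d. uniform, GC-rich or FASTA-derived backgrounds),
    positive-predictive-value benchmarking of statistics, and
    distance-based phylogeny reconstruction (neighbor joining, UPGMA)
    scored with the Robinson-Foulds distance.  Pattern extraction runs
    on a generalized suffix array with LCP support in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
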