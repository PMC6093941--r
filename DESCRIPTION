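Package: dedocr
Title: Normalization-Free TAD Calling by Structural Entropy Minimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects topologically associating domains (TADs) in Hi-C
    contact matrices by treating the matrix as a weighted graph and greedily
    minimizing the structural entropy of a two-level coding tree, without any
    matrix normalization. Provides the coding-tree machinery (node and tree
    structural entropy, merging and combining operators with incremental
    entropy deltas), the deDoc(E) and deDoc(M) calling modes with contiguity
    handling, a structural-entropy-based binsize (resolution) selector, the
    weighted-similarity metric for comparing domain partitions, readers and
    writers for common plain-text Hi-C matrix dialects and BED output, a
    seeded generator of Hi-C-like matrices with planted domains and binomial
    read thinning, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
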