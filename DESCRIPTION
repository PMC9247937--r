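Package: pcv
Title: Alignment-Free Protein Sequence Comparison via Physicochemical
    Block Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes fixed-length blocks of protein sequences as
    concatenations of physicochemical property sums and second
    positional moments built on clustered AAindex amino-acid indices,
    and scores pairwise sequence dissimilarity as the sum over blocks
    of the shift-minimised Euclidean distance between block encodings.
    Includes an AAindex1 flat-file parser, correlation-space
    complete-linkage property clustering, UPGMA and neighbor-joining
    tree construction, Robinson-Foulds and matrix-correlation tree and
    matrix comparison, pairwise ROC/AUC evaluation against class
    labels, and seed-deterministic synthetic generators for property
    tables and sequence families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
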