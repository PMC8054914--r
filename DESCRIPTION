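Package: clonecensus
Title: Consensus Reconstruction of Subclonal Tumor Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for intra-tumor heterogeneity analysis from bulk
    whole-genome sequencing summaries. Simulates tumors with known subclonal
    architecture and binomial read counts, clusters single-nucleotide variants
    by cancer cell fraction, combines clusterings from multiple methods into a
    consensus architecture (weighted-median of CDFs, assignment-vector
    clustering, and co-clustering matrix factorization), corrects the winner's
    curse detection bias of low-frequency subclones, builds consensus
    copy-number breakpoints, segment calls and purity from multiple callers,
    classifies phased SNV pairs into linear versus branching phylogeny
    evidence, tracks mutation-signature activities along pseudo-time with
    change-point detection, and scores reconstructions against simulated
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
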