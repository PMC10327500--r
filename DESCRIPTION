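Package: plasmidhost
Title: Alignment-Free Plasmid Host-Range Prediction from Genomic
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the evolutionary host range of plasmids from
    nucleotide composition alone.  Computes both-strand canonical k-mer
    signatures normalized by background base composition (the rho
    statistic), models the distribution of signatures across
    non-overlapping chromosomal segments, and scores each
    plasmid-chromosome pair with the Mahalanobis distance and its
    chi-square P-value; chromosomes with P-value above 0.6 are flagged
    as evolutionary host candidates.  Also provides Euclidean
    clustering of plasmid signatures and a seeded Markov-chain genome
    simulator for fully reproducible benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
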