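Package: felscan
Title: Codon-Level Selection Analysis with FEL and MG94xREV Aggregate Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Site-level dN/dS estimation for protein-coding alignments using the
    fixed effects likelihood (FEL) approach under an MG94xREV codon substitution
    model, with profile-likelihood confidence intervals, partition-level
    aggregate omega estimation, one-degree-of-freedom likelihood-ratio
    comparisons between genes or partitions, and Hasse-diagram summaries of the
    resulting partial order. Includes the sequence-curation rules used to build
    ortholog codon alignments (pairwise global protein alignment with
    identity/similarity thresholds, canonical-start trimming, ortholog-group
    assignment by tree clustering) and a forward codon simulator with
    site-specific selection profiles for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
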