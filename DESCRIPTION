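Package: phylograft
Title: Phylogenomic Screening for Endosymbiotic and Horizontal Gene Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phylogenomic screen for endosymbiotic and horizontal gene
    transfer (E/HGT) in gene families, modelled on the workflow used to trace
    red and green algal ancestry of diatom membrane transporters. Builds
    homolog sets by reciprocal-hit intersection with taxonomic sampling
    filters, sorts bootstrap-annotated gene trees by support-aware monophyly
    with outgroup rooting rules, classifies per-tree gene origin, constructs
    constrained null topologies by prune-and-regraft, and compares topologies
    with KH, SH and expected-likelihood-weight tests on RELL-resampled
    per-site log-likelihoods under WAG with discrete-gamma rates. Includes a
    synthetic-data generator with known transfer histories for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
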