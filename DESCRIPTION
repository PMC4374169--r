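Package: haplomix
Title: Haplotype Painting and Ancestry Mixture Decomposition for Admixed
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Paints target genomes as mosaics of donor haplotypes with a
    Li-Stephens copying hidden Markov model, clusters donor individuals into
    genetically homogeneous groups from chunk-count matrices with a
    Dirichlet-multinomial partition MCMC, decomposes recipient copying
    vectors into non-negative donor-cluster mixture proportions (with
    surrogate-donor masking and leave-one-chromosome-out jackknife standard
    errors), and summarizes relative continental ancestry with Ward
    hierarchical clustering and bootstrap consensus trees. Includes a
    synthetic-data generator producing phased donor pools with population
    structure and admixed recipients with known mixing proportions and
    ancestry tracts, so the whole pipeline is testable without external
    genotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
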