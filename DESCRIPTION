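Package: nifhnet
Title: Co-Occurrence Networks of Nitrogen-Fixing Bacteria and Wood-Decaying Fungi
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline linking diazotroph (nifH) amplicon diversity in dead
    wood to fungal sporocarp communities. Provides degenerate-primer trimming
    and greedy 97%-identity MOTU clustering of nifH amplicons with consensus
    protein inference; distance-based community statistics (Bray-Curtis
    perMANOVA, multivariate regression trees, PCA of group means, richness
    regressions with backward selection, k-means decay classes); presence-
    absence null models (C-score, checkerboard statistics, fixed-fixed
    sequential swap randomization, pairwise Z-scores); and assembly and export
    of signed fungus-diazotroph association networks. A synthetic-data
    generator emulating a 45-log two-tree-species study design makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    vegan,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Network, Clustering, Sequencing
RoxygenNote: 7.3.3
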