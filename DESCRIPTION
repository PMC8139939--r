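Package: splitcover
Title: Universal Tree Sets and Incompatibility of Phylogenetic Split Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the incompatibility of phylogenetic split systems by
    the minimum number of unrooted trees needed to display every split. Computes
    the universal incompatibility U(n) (the minimal size of a tree set displaying
    all splits on n taxa) in closed form and constructively, via symmetric chain
    decompositions of the subset lattice and maximum matchings on the
    compatibility graph of the maximum-size bipartitions. For arbitrary split
    systems (including those parsed from SplitsTree-style NEXUS files) it
    computes the largest pairwise-incompatible subset (k-compatibility), the
    exact minimal tree set size kappa as a minimum partition into
    pairwise-compatible classes, and the normalized tree set size kappa/U(n)
    which makes incompatibility comparable across taxon counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
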