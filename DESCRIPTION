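Package: dcnet
Title: Divide-and-Conquer Construction of Rooted Phylogenetic Networks from Cluster Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds rooted phylogenetic networks that represent a set of
    clusters (clades extracted from rooted gene trees) in the softwired
    sense.  The construction divides the incompatibility graph of the
    clusters into connected components, collapses maximal strict tree sets
    (ST-sets), and resolves each small component by lookup in a catalog of
    canonical simplest cluster sets with precomputed minimal networks,
    transferring the stored network back by taxon relabeling and
    decollapsing.  Also provides the verification machinery (softwired and
    hardwired representation, reticulation numbers, the decomposition
    property) and an exhaustive enumeration oracle for isomorphism classes
    of simplest cluster sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
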