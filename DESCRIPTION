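Package: netclasses
Title: Classes of Rooted Binary Phylogenetic Networks: Predicates, Leaf
    Restriction, Enumeration and Asymptotic Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A combinatorial toolkit for rooted binary phylogenetic
    networks. Provides membership predicates for the standard network
    classes (trees, tree-child, normal, galled networks, galled trees,
    simplicial and semi-simplicial networks), the induced-subnetwork
    operator that restricts a network to a subset of its leaves,
    machinery to test whether a class is closed under leaf restriction
    and to locate the maximal closed subclass empirically, exhaustive
    enumeration of all labeled networks for small leaf and reticulation
    numbers, exact big-integer counting sequences, a registry of
    first-order asymptotic growth forms with Laplace-method transfer of
    binomial convolutions, and Monte-Carlo experiments on pendant
    subtree-shape containment in uniform random trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
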