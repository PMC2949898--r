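Package: biorder
Title: Bi-Ordering Analysis of Gene Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory bi-ordering analysis of gene expression matrices.
    Implements the BOA fixed-point biclustering algorithm (over-expressed,
    under-expressed and fixed-size variants) with a random-initialization
    protocol, consensus grouping of converged biclusters into super-biclusters
    by gene-set Jaccard similarity, and statistical figures of merit:
    single- and multiple-class saturation p-values based on the
    hypergeometric distribution, and the Jonckheere trend test for monotone
    association between sample orderings and ordinal clinical annotations.
    Includes a synthetic data generator that plants constant-shift biclusters
    in Gaussian noise for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
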