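Package: asaq
Title: Algebraic and Semi-Algebraic Quartet Weighting and Tree Amalgamation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quartet-based phylogenetic tree reconstruction under the general
    Markov model. Implements the paralinear (log-det) quartet statistic and its
    weighting system, flattening-rank scores with across-site mixture support,
    semi-algebraic quartet scores, and the combined ASAQ weighting rule, together
    with weighted quartet amalgamation heuristics (weight optimization, quartet
    puzzling, consistency-count insertion), majority-rule consensus, and a
    simulation framework for non-homogeneous Markov and homogeneous GTR
    alignments on quartets and 12-taxon benchmark trees.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
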