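Package: quartetNMSC
Title: Quartet Scores and Species-Tree Inference Under the Network
    Multispecies Coalescent
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying quartet-score based species-tree inference
    when gene trees arise from a hybridization network rather than a tree.
    Implements closed-form quartet gene-tree topology probabilities under
    the multispecies coalescent (MSC) and under the network multispecies
    coalescent (NMSC) for 5-taxon single-cycle networks, expected quartet
    scores with an exact maximizer over all 15 unrooted 5-taxon topologies,
    executable inequality conditions delimiting the parameter region in
    which a non-displayed tree outscores both displayed trees, Monte-Carlo
    scans of that region, and a coalescent gene-tree simulator that
    validates the analytic theory empirically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
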