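Package: quartetpp
Title: Quartet-Based Branch Support and Coalescent Branch Lengths for Species Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the internal branches of a species tree against a
    collection of gene trees under the multi-species coalescent. For each
    branch it computes averaged quartet frequencies for the three possible
    resolutions, converts them into local posterior probabilities under a
    Yule prior on branch lengths, and estimates maximum-likelihood and
    maximum-a-posteriori branch lengths in coalescent units. Handles
    multifurcating gene trees and missing taxa, collapses low-support
    gene-tree branches, and includes a multi-species-coalescent simulator
    (Yule species trees, coalescent gene trees, topological noise, taxon
    deletion) plus evaluation metrics for support calibration and
    branch-length accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
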