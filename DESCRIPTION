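Package: drugsig
Title: Consensus Drug-Repurposing Prediction and Benchmarking from
    Interaction Signatures
Version: 0.1.0
Authors@R:
    person("Drugsig", "Maintainers", email = "maintainers@drugsig.org",
           role = c("aut", "cre"))
Description: Tools for drug repurposing by interaction-signature similarity:
    compound-protein interaction matrices built from binding-site libraries
    under three scoring types, all-against-all signature similarity lists,
    consensus ranking of candidate compounds for an indication, and dual
    benchmarking protocols (similarity-list indication accuracy and
    leave-one-out consensus recovery with nIA/nAIA/nNDCG) with hypergeometric
    and randomized-matrix null controls, grouped parameter optimization,
    performance-feature correlation analysis, a synthetic data generator with
    planted indication clusters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
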