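Package: bmlp
Title: Boolean Matrix Logic Programming for Metabolic Networks and
    Cost-Aware Active Learning of Gene Function
Version: 0.1.0
Authors@R:
    person("Metabolic", "Logic Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates recursive datalog encodings of genome-scale
    metabolic networks with Boolean matrix kernels (an
    iterative-extension fixpoint over reactant/product matrices),
    predicts auxotrophic knockout phenotypes from gene-protein-reaction
    rules, and recovers masked gene-function and isoenzyme annotations
    with a compression-guided, cost-sensitive active-learning loop over
    a finite hypothesis space. Includes a seeded generator of layered
    synthetic metabolic models with reagent costs for fully offline
    benchmarking, plus a small command-line surface for reproducible
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
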