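Package: kgppi
Title: Hybrid Knowledge-Graph Link Prediction and Literature Validation for
    Protein-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expands associative gene networks with new protein-protein
    interactions by combining three stages: node embeddings learned with a
    GraphSAGE-style neighbourhood-aggregation link predictor, a multilayer
    perceptron that fuses two node embeddings with a literature co-occurrence
    feature to score candidate pairs, and a pluggable instruction-prompt text
    validator that confirms predicted pairs against the abstracts that mention
    them. Ships a seeded synthetic-world generator (planted-partition graph,
    co-occurrence table, templated abstract corpus, ground truth) so the whole
    pipeline is testable offline, plus confusion-matrix bookkeeping with the
    six standard evaluation metrics including the Matthews correlation
    coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
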