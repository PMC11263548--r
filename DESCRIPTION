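Package: s4clm
Title: Structured State-Space Chemical Language Models for De Novo Molecule Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A chemical language model built on structured state-space (S4)
    sequence layers for de novo SMILES design. The state-space layer is
    trained as a global causal convolution over whole molecular strings and
    switched to an equivalent linear recurrence for token-by-token
    generation. Includes SMILES tokenization, corpus curation and vocabulary
    handling, next-token pre-training and transfer-learning fine-tuning with
    early stopping, temperature-controlled sampling, joint log-likelihood
    scoring with bias correction for ranking and enrichment analysis,
    design-quality evaluation (validity/uniqueness/novelty, syntax-error
    taxonomy, property profiles with Kolmogorov-Smirnov distances,
    rediscovery, scaffold clustering), a synthetic-fixture generator, and a
    command-line interface. Molecule parsing, descriptors, fingerprints and
    scaffolds are delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
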