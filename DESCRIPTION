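Package: dtimoa
Title: Mode-of-Action Drug-Target Interaction Prediction from Genetically
    Perturbed Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts activatory and inhibitory drug-target interactions by
    combining substructure-based compound embeddings with consensus target
    vectors derived from genetically perturbed transcriptome signatures.
    Implements correlation-weighted (MODZ-style) signature aggregation in two
    stages (experimental condition, then cell line), extension of the target
    space by weighted averaging over protein-protein interaction neighbours,
    Morgan-substructure sentence embeddings of compounds, a cascade deep
    forest classifier with data-driven level selection, and a virtual
    screening evaluation protocol (repeated cross-validation with asymmetric
    negative sampling, AUROC/AUPR, enrichment factors, and
    reference-distribution ranking). A synthetic data generator provides
    replicate signatures, planted PPI neighbourhoods, embedding tables and
    benchmark interaction labels so the full pipeline runs without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ranger,
    nnet,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
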