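Package: LiGhT
Title: Knowledge-Guided Line-Graph Transformer for Molecular Representation Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-supervised molecular representation learning with a
    line-graph transformer. Molecules parsed from SMILES are converted to
    molecular line graphs (nodes are chemical bonds) augmented with a
    knowledge node carrying 200 molecular descriptors and a 512-bit
    path-based fingerprint. A transformer encoder with shortest-path and
    distance attention biases is pre-trained with a masked-graph objective
    (masked node-type recovery plus masked-knowledge regression and
    fingerprint classification) and transferred to property-prediction
    tasks via finetuning strategies (layer-wise learning-rate decay,
    re-initialization, adversarial feature augmentation, L2-SP) or frozen
    neural-fingerprint extraction. Includes scaffold splitting, evaluation
    metrics, and a deterministic drug-like fixture-molecule generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
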