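Package: pathattn
Title: Interpretable Cell-Type Annotation with Pathway-Token Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised transfer of cell-type labels from a reference
    single-cell RNA-seq dataset to query datasets using a transformer
    whose first layer is a knowledge-masked linear embedding: genes are
    mapped onto pathway (or regulon) tokens through a binary gene-set
    membership mask, a class token attends to the pathway tokens through
    multi-head self-attention, and the class-token representation drives
    a softmax cell-type classifier. The post-softmax attention of the
    class token over pathway tokens is exposed as an interpretable,
    batch-insensitive per-cell embedding. Includes "Unknown" calling for
    novel cell types below a probability cutoff, differential-attention
    marker tests, gene-importance tracing from tokens back to genes,
    dataset-difficulty statistics (label entropy, reference/query
    Kullback-Leibler divergence), and a negative-binomial pathway-driven
    count simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
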