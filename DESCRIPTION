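Package: mdanet
Title: miRNA-Disease Association Prediction via Attributed Network Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate microRNA-disease associations by embedding an
    attributed bipartite association network. Known associations define the
    network structure; miRNA sequence similarity (k-mer cosine) and disease
    semantic similarity (weighted ancestor overlap on a disease hierarchy)
    define node attributes. Structure and attribute transition matrices are
    fused and accumulated over several random-walk orders into an enhanced
    proximity matrix, compressed per node with a stacked auto-encoder, and
    node-pair feature vectors are scored with a random forest. Includes a
    planted-partition synthetic data generator, masked cross-validated
    evaluation with ROC/PR metrics, and candidate ranking for a disease.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    randomForest,
    e1071,
    class,
    rpart,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
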