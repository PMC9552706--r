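Package: lncMirProj
Title: Similarity Fusion and Network Consistency Projection for
    lncRNA-miRNA Association Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scores unknown lncRNA-miRNA pairs from a binary association
    matrix by fusing three interaction-profile similarity kernels (cosine,
    Jaccard, and a self-tuning spectral-clustering affinity) on both sides
    of the bipartite network and combining the lncRNA-space and miRNA-space
    network consistency projections into a single normalized prediction
    score. Provides leakage-safe k-fold and leave-one-out cross-validation
    with pooled ROC/AUC and precision-recall summaries, ranked candidate
    export, and a seeded planted-block synthetic association generator for
    offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
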