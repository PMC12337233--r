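Package: llmsynergy
Title: Boosting-Weighted Majority Voting and Cluster-Based Dynamic
    Selection for Ensembles of Frozen Question-Answering Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines the cached categorical answers of several frozen
    base models (for example zero-shot large language models) on
    multiple-choice question-answering tasks. Provides a boosting-style
    weighted majority vote that learns one log-odds-based weight per base
    model, and a cluster-based dynamic model selection that clusters
    question-context embeddings with k-means (K chosen by mean silhouette
    with elbow confirmation) and learns separate voting weights per
    cluster, with validation-driven tuning of K. Includes a deterministic
    hashing text embedder, JSONL/CSV readers for datasets and prediction
    matrices, stratified train/validation splitting, an evaluation
    harness with a train/test leakage guard, and a synthetic-universe
    generator for simulating base predictors with cluster-dependent
    accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
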