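Package: grnscore
Title: Ensemble Gene Regulatory Network Inference and Network-Based
    Regulator Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor to target-gene regulatory networks
    from a normalized expression matrix with an ensemble of five algorithms
    (Pearson and Spearman correlation, CLR, ARACNe and a GENIE3-style tree
    ensemble), combines them into a consensus network by average-rank
    aggregation, detects co-regulated gene modules by Jaccard projection and
    Markov clustering, and prioritizes regulators with a linear-margin
    support vector machine trained on TF-by-module connectivity features.
    Includes reference-network builders and precision/recall evaluation
    utilities, a seeded synthetic-data generator with a modular ground-truth
    network for end-to-end benchmarking, and a one-command pipeline with a
    reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
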