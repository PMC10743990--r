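Package: consensusVS
Title: Consensus Machine-Learning Virtual Screening for Kinase Inhibitor Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ligand-based virtual screening with fingerprint classifiers and
    probability-averaging consensus scoring. Curates bioactivity tables
    (IC50/Ki) into binary-labeled datasets with replicate outlier removal and
    potency thresholds, computes seven molecular representations (circular,
    subgraph, layered, pattern, 2D-pharmacophore and substructure-key
    fingerprints plus physicochemical descriptors), trains and tunes Random
    Forest, Support Vector Machine (including a Tanimoto kernel), k-Nearest
    Neighbor and Multi-layer Perceptron classifiers on printed hyperparameter
    grids, combines them into a consensus score, runs a multi-filter
    screening funnel (consensus cutoff, Tanimoto novelty filter,
    sphere-exclusion clustering, PAINS alerts) and explains predictions at
    atom resolution by permutation Shapley attribution retro-mapped from
    fingerprint bits to atoms. Includes a synthetic activity-table generator
    with planted structure-activity signal so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ChemmineR,
    ChemmineOB,
    randomForest,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Cheminformatics, MachineLearning, Classification
RoxygenNote: 7.3.3
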