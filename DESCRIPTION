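Package: kingdomFuse
Title: Multi-Kingdom Gut Microbiome Subtyping by Weighted Similarity Network Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates bacterial, archaeal, fungal and viral abundance tables
    into a single patient similarity network by weighted similarity network
    fusion (WSNF), selects the number of subtypes by silhouette-scanned
    spectral clustering, and characterizes the resulting subtypes: alpha/beta
    diversity with a permutation PERMANOVA, treatment-response and survival
    contrasts (Kaplan-Meier, log-rank), negative-binomial Wald differential
    abundance with per-kingdom fold-change thresholds and panel selection,
    random-forest and support-vector subtype classifiers with cross-validated
    ROC/AUC, and SparCC compositional co-occurrence networks with bootstrap
    p-values. Ships a synthetic multi-kingdom data generator with planted
    subtypes, outcomes and taxon-taxon correlations so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    vegan,
    randomForest,
    e1071,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    survival,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
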