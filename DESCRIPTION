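Package: vshybrid
Title: Hybrid Graph Neural Network and Descriptor Models for Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening with graph neural network molecular
    encoders whose learned representation is concatenated with expert-crafted
    molecular descriptors before classification. Provides molecule input/output
    with validity filtering and deduplication, graph featurization, a built-in
    descriptor set plus an importer for external descriptor tables, GCN and
    SchNet encoders with a registry for extensions, training of hybrid and
    baseline models under binary cross-entropy, random and Bemis-Murcko
    scaffold train/test splitting, the early-recognition evaluation metrics
    used in virtual screening (ranged logarithmic ROC AUC, BEDROC, enrichment
    factor and discounted cumulative gain at cutoff 100), paired model
    comparison with FDR adjustment, and a synthetic high-throughput-screening
    data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
SystemRequirements: OpenBabel (the 'obabel' executable on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
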