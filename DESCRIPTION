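Package: mddnet
Title: Tripartite Microbe-Drug-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts unobserved microbe-disease and microbe-drug associations
    and extracts disease-microbe-drug triples from curated bipartite
    association networks. Builds Gaussian interaction-profile kernel
    similarities from association topology, biological similarities from
    genome gene-family content and connectivity, symptom TF-IDF cosine
    profiles and fingerprint Tanimoto coefficients, fuses them by conditional
    averaging, featurizes the fused networks with random walk with restart,
    scores candidate links by similarity-weighted neighbor voting, and exports
    the resulting tripartite network in SIF, GraphML and TSV formats. Includes
    a deterministic synthetic-data generator with planted block structure so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
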