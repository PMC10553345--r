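Package: netpattern
Title: Cross-System Knowledge-Network Profiles and Trend Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a four-measure structural profile (average degree,
    average PageRank, average clustering coefficient, average per-node
    triangle membership) uniformly across very different "knowledge
    processing" networks: fired-neuron subgraphs extracted from a sigmoid
    multilayer perceptron during training, cumulative yearly topic
    co-occurrence networks built from publication records, four classical
    random-graph models grown over iterations, and animal connectomes with
    density-matched Erdos-Renyi null models. Trajectories of the profile
    over epochs, years or graph size are classified as Up/Down/Flat and
    assembled into a cross-system trend summary. Includes seeded synthetic
    generators for all three input kinds so the full pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
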