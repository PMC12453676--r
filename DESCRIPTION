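Package: mdembed
Title: Contact-Graph Embeddings and Conformational-State Classification
    for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("mdembed", "developers", email = "mdembed@example.org",
           role = c("aut", "cre"))
Description: Converts each frame of a protein molecular-dynamics trajectory
    into a cutoff-filtered, distance-weighted alpha-carbon contact graph,
    learns per-frame node embeddings by biased random walks (node2vec) or
    neural aggregation (GCN, GAT, GraphSAGE), flattens the embedding
    matrices into a per-frame feature table, derives conformational-state
    labels by principal-component projection and kernel-density
    thresholding, and trains and evaluates supervised classifiers of
    conformational state. Includes a synthetic multi-state hinge-peptide
    ensemble generator with ground-truth labels so the full pipeline is
    testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    glmnet,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
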