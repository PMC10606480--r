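Package: hemlink
Title: Link Prediction via Hybrid Network-Evolution-Mechanism Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Similarity-based link prediction on undirected networks, built
    around three indices derived from classical network evolution mechanisms
    (degree balancing on regular networks, difference-preferential attachment
    on scale-free networks, and bounded walk counts on small-world networks)
    and their parametric hybrid combination, HEM. Includes seeded generators
    for random regular, Barabasi-Albert and Watts-Strogatz/Newman-Watts
    models, a comparison bank of common-neighbour, path-based and global
    similarity indices, a 10-fold edge cross-validation harness with
    exhaustive and sampled AUC and precision-at-L, a parameter grid scan for
    the hybrid index, and two diagnostic methods that relate the dominant
    prediction factor to network features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
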