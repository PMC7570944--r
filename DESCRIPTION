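Package: herdrank
Title: Rank-Based Social Structure Analysis for Tracked Animal Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies social attraction and repulsion in a group of
    simultaneously tracked animals from planar trajectory data. Builds the
    time-averaged distance-rank closeness matrix and the reciprocal-rank
    variation matrix, embeds their product-symmetrised dissimilarities by
    classical multidimensional scaling, clusters animals with
    silhouette-selected K-means and with an agglomerative hierarchy driven by
    an indegree-outdegree affinity, and derives per-timeslot spatial herd
    statistics (time alone, co-membership, cluster-size budgets, connectors).
    Includes a synthetic herd simulator with planted leader, follower and
    loner roles for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
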