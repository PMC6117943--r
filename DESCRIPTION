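Package: dinet
Title: Differential Network Analysis over Background Knowledge Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable toolkit for differential network analysis of
    multi-condition omics experiments over a curated background knowledge
    network. Reads networks from delimited node/edge tables, GraphML and
    XGMML (coordinates); simplifies networks and assigns deterministic
    grid-seeded layouts; partitions large networks with multi-level
    modularity optimisation followed by spinglass sub-clustering, with
    structural classification of clusters into densely connected and
    star-like types; overlays per-condition weight/significance
    measurements to construct condition-specific active subnetworks with a
    saturating edge-weight score, red-blue visual encoding, degree
    filtering and functional-bin enrichment; interpolates node and edge
    weights between consecutive conditions (linear homotopy) into frame
    sequences for animation; and writes a reproducibility settings log
    that can be replayed and checksum-verified.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
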