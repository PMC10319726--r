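Package: keystone
Title: Top-Down Identification of Keystone Taxa in Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate keystone taxa in microbial communities from
    their total influence on the rest of the community, without
    reconstructing the inter-specific interaction network. Provides a
    generalized Lotka-Volterra (GLV) community simulator with designated
    artificial keystones (interaction-strength boosts on Erdos-Renyi
    topologies and natural hubs of directed Barabasi-Albert topologies),
    an in-silico addition/removal perturbation assay that measures each
    taxon's presence-impact as the dissimilarity between renormalized
    community profiles before and after the perturbation, three empirical
    presence-abundance interrelation (EPI) measures for cross-sectional
    relative-abundance tables (mean cross-group distance, distance
    between group means, and the modularity of a presence-labelled
    sample-similarity network), a longitudinal EPI for paired
    two-time-point cohorts, and presence/absence co-occurrence networks
    built from normalized mutual information for detecting keystone
    modules. Includes fixed-margin (checkerboard-swap) null shuffling,
    frequency filtering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    vegan,
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
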