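Package: invasinet
Title: Roles of Non-Native Species in Mutualistic Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of the positions of non-native species in binary
    bipartite mutualistic networks (pollination and seed dispersal).
    Provides an annotated incidence-matrix data model with readers and
    writers, species- and network-level metrics (normalized degree,
    projection betweenness and closeness, Pollination Service Index,
    connectance, mean links, generality, vulnerability), targeted and
    matched-random species removals, fixed-dimension fixed-fill null
    models, one-step and cascading secondary-extinction simulation,
    paired t-test and mixed-effects comparisons across network
    collections, and a synthetic network generator emulating invaded
    mutualistic communities, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
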