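Package: ratchetr
Title: Agent-Based Simulation of Cumulative Cultural Evolution and Social Ratcheting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cumulative cultural evolution in kin-structured
    populations of tool-making agents. Agents hold toolkits drawn from four
    technological lineages, choose recombination partners by toolkit
    dissimilarity (Jaccard distance), create new tools by incremental
    recombination or cross-lineage crossovers on a deterministic fitness
    ladder, and optionally transmit innovations along kin-weighted network
    links under a hard memory cap. Includes the full measurement suite
    (entropy-based specialization, Jaccard differentiation at agent and
    group level, network interconnectivity, ego-network interdependence)
    and a scenario/replicate runner for factorial memory-by-transmission
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
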