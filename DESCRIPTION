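Package: superspreadr
Title: Community-Aware Selection of Multiple Influential Spreaders in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies a set of k influential spreader nodes in an undirected
    network with community structure by aggregating the network into "super
    nodes" with a single pass of the Louvain modularity procedure and then
    sweeping the super nodes in decreasing size order, picking at most one
    high-centrality spreader per super node under an adjacency-exclusion rule.
    Includes the discrete-time SIR contact-process simulator used to measure
    influence scope, benchmark selectors (top-k and unconnected top-k by
    centrality, and a bond-percolation k-medoid comparator), growth- and
    coverage-ratio evaluation metrics, and LFR-style synthetic network
    generators with planted power-law communities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
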