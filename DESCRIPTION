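Package: ledgm
Title: Local Effective Distance-Integrated Gravity Model for Influential
    Node Identification
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies influential spreader nodes in undirected networks
    with a gravity-model centrality whose node mass fuses degree, k-shell
    coreness and local clustering, and whose distance is the asymmetric
    effective distance derived from transition probabilities, truncated to
    each node's effective-influence set. Ships the comparator centralities
    (degree, betweenness, closeness, k-shell, plain and generalized gravity
    models, effective-distance gravity model), a discrete-time
    susceptible-infected spreading simulator used as ground truth for
    spreading power, Kendall tau-a ranking evaluation, Erdos-Renyi
    generators, edge-list and adjacency-matrix readers and writers, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
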