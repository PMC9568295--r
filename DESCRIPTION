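Package: topodnn
Title: Degree-Based Topological Indices of Layered Neural-Network Graphs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes twelve degree-based topological indices (Randic,
    general Randic, first and second Zagreb, multiplicative Zagreb,
    hyper-Zagreb, forgotten, atom-bond connectivity, sum-connectivity,
    geometric-arithmetic and augmented Zagreb) for arbitrary undirected
    simple graphs and, in closed form via the edge-partition method, for
    the layered complete-bipartite graph family that models fully
    connected deep neural networks DNN(M; N1..Nr; N). Multiplicative
    indices are carried as exact arbitrary-precision integers with a
    log10 companion. Includes edge-list TSV input and output, a
    brute-force oracle for verifying the closed forms, depth-sweep
    growth profiles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
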