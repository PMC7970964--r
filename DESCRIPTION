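Package: structnet
Title: Sparse Neural Networks from Biological and Random Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how much of a neural network's function lives
    in its wiring. Converts directed signed graphs -- random G(n,p) and
    small-world graphs, the C. elegans micro-connectome, thresholded human
    macro-connectome matrices, and synthetic stand-ins for all of them --
    into trainable masked feed-forward and recurrent networks. Implements
    dense-to-ternary sparsification at a target mean degree, structure
    implantation and winning-ticket initialization, iterative and stochastic
    ("bio") pruning, SGD training with disturbed or blocked parameters, and
    the comparison analytics: Spearman weight and offset similarity, odd-edge
    counts, degree-sequence isomorphism screening, labeled-graph counting via
    log-gamma, learn-curve statistics with one-sided t-tests and Bonferroni
    correction, and paired-triangle ("toast") comparison matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
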