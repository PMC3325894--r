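Package: pecnet
Title: Essential Protein Prediction from Interaction Networks and Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts essential proteins from a protein-protein interaction
    network by integrating topology with gene-expression data. Implements the
    PeC centrality, which scores each protein by the summed probability of
    being co-clustered (edge clustering coefficient) and co-expressed
    (Pearson correlation) with its network neighbors, together with a suite
    of thirteen classical comparison centralities, a jackknife ranking
    evaluation with random baselines, top-k precision and overlap reports,
    and a synthetic fixture generator that emulates the cluster-plus-hub
    structure of real interactomes.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
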