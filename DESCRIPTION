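Package: pathcomm
Title: Path-Centric Graph Transformer for Intra- and Inter-Cell
    Communication Inference from Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies single cells between two conditions with a graph
    transformer that operates on a role-annotated gene-gene interaction
    graph, scores predefined receptor-anchored signaling paths through a
    trainable, expression-prior-regularized importance vector, and merges
    the top-ranked paths into intra-cell signaling networks that can be
    linked across cell types via ligand-receptor pairs to form inter-cell
    communication networks. Includes a synthetic single-cell data
    generator with planted differentially expressed paths for end-to-end
    benchmarking of path recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
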