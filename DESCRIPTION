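Package: scAtlasTree
Title: Progressive Cell-Type Hierarchy Construction and Hierarchical
    Label Transfer for Integrated Single-Cell Atlases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds, extends and applies cell-type hierarchies for
    collections of labeled single-cell datasets that share an integrated
    low-dimensional latent space. Cell types are matched across datasets
    by training a k-nearest-neighbour classifier per dataset,
    cross-predicting labels, and resolving the binarized confusion
    matrices into perfect matches, subpopulations, merges and novel
    populations; the resulting tree doubles as a hierarchical classifier
    with per-node rejection of ambiguous (posterior probability) and
    novel (neighbour distance, PCA reconstruction error) cells. Includes
    a synthetic latent-space generator with known ground-truth
    hierarchies, an ancestor-descendant edge-graph comparison for
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
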