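Package: mazembed
Title: Euclidean Embedding of Labeled Place Graphs and Cognitive-Map Model
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing cognitive-map models of spatial memory.
    Represents a corridor maze (optionally containing wormholes, i.e. seamless
    teleports with rotation that make the environment non-Euclidean), builds a
    non-metric labeled place graph from the egomotion experienced along its
    corridors, embeds the graph into 2D Euclidean coordinates by multi-restart
    quasi-Newton minimization of a triplet stress function, derives shortcut
    direction predictions under the non-metric, embedded and ground-truth
    models, and compares the models against (synthetic or recorded) human
    directional estimates with circular statistics (Rayleigh and
    Watson-Williams tests, von Mises noise models) and the Bayesian
    information criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
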