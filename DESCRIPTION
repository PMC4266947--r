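Package: sstree
Title: Score Aggregation over Unbalanced Signed Graphs by Spanning-Tree Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aggregates real-valued nodal scores (for example gene differential
    expressions or node-level perturbation amplitudes) over signed causal
    network models. On balanced ("causally consistent") graphs the aggregate is
    the sign-weighted sum of nodal scores relative to a reference node. On
    unbalanced graphs, where relative nodal signs are path-dependent, the rigid
    nodal sign is replaced by a continuous effective weight in [-1, 1] obtained
    by averaging path signs over the graph's spanning trees, either exactly by
    enumeration (matrix-tree counting, contraction-deletion enumeration) or by
    Monte-Carlo sampling of uniform spanning trees with signed random walkers
    (Aldous' first-entrance method). Includes balance diagnostics, a
    most-representative-tree summary, classification metrics against reference
    sign assignments, and generators for synthetic signed graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), pROC, withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
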