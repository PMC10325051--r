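Package: kinasecomm
Title: Community Detection in Empirical Kinase Networks from
    Perturbation Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds weighted, undirected kinase-kinase networks from
    inhibitor-perturbation phosphoproteomics z-scores, detects communities
    by modularity maximisation under uniform or Newman-Girvan null networks
    (nondeterministic Louvain heuristic with consensus clustering over
    iterated co-classification matrices), and nominates candidate members of
    canonical signalling pathways by community strength and anchor-edge
    filtering. A planted-partition synthetic z-score generator with
    calibrated negative-tail statistics makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
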