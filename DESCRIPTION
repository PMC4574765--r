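Package: pathwaylens
Title: Pathway Graphs, On-Demand Differential Expression and Expression Overlays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Back-end toolkit for exploring two-group gene expression data in
    the context of KEGG pathways. Parses KGML pathway documents into a typed
    graph model with pixel-space node graphics, computes per-gene fold
    changes, Welch t-tests and Benjamini-Hochberg adjusted p-values on
    demand, maps the statistics onto node fill and significance-frame
    colors for pathway visualization, and exposes the results through a
    small read-only HTTP data interface (/genes, /fc, /pvalues, /exprs,
    /pathway). A disk-backed client caches every remote KEGG resource so
    the whole pipeline runs offline, and a synthetic-data module generates
    expression matrices with planted effects plus matching KGML fixtures
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
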