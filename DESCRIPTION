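Package: pgcna
Title: Parsimonious Gene Correlation Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds merged multi-dataset gene co-expression networks by
    aggressive per-gene edge reduction (edges-per-gene, EPG), clusters them
    into modules by repeated Louvain modularity optimisation, scores
    candidate clusterings with a scaled cluster enrichment score (SCES)
    based on hypergeometric gene-signature enrichment, and derives
    per-sample module expression values (MEVs) from ModCon-ranked hub genes
    for downstream sample stratification, survival meta-analysis and
    expression-mutation association. Includes a seeded synthetic-data
    generator with planted modules so the whole pipeline can be exercised
    and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    survival,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    metafor,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
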