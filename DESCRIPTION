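Package: kgroups
Title: Knowledge Spreadsheets over Pathway/Genome Knowledge Bases
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tabular "groups" of knowledge-base objects (genes, pathways,
    compounds, promoters, sequence regions) with multi-valued cells,
    semantic column transformations that traverse the relations of a
    frame-based pathway/genome knowledge base, set and filter algebra,
    tab-delimited import/export with identifier resolution, persistent
    group storage, and gene-set enrichment analysis (Fisher exact and
    parent-child union/intersection variants with Bonferroni,
    Benjamini-Hochberg and Benjamini-Yekutieli corrections). Ships a
    deterministic synthetic pathway/genome database generator and a small
    hand-authored fixture for examples and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, Biostrings, igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
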