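Package: conservomics
Title: Cross-Species Multiomics Integration of Lens Differentiation States
Version: 0.1.0
Authors@R:
    person("Conservomics", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating differential gene expression and
    differential chromatin accessibility across two species to identify
    evolutionarily conserved regulatory programs of lens epithelial and
    fiber cells. Provides differentiation-state gene classification,
    ortholog-aware conservation tests (hypergeometric), strand-aware
    promoter-window chromatin-state classification of differential
    ATAC-seq peaks, nearest-TSS peak assignment, position-weight-matrix
    motif scanning with Fisher-type enrichment and a four-way
    conserved-class motif partition, curated gene-set overlap statistics,
    and a fully self-contained two-species synthetic fixture generator
    with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
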