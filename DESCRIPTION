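Package: dichroma
Title: Temporal Expression Dynamics and Structural Compatibility of
    Protein Complexes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for time-course gene expression
    studies of cellular differentiation. Classifies genes into
    non-dynamic, dynamic and super-dynamic categories with a
    chi-squared time-course statistic calibrated by a universal error
    term, clusters temporal profiles by K-means with silhouette and
    pseudo-F model selection, quantifies co-expression divergence of
    paralogous gene pairs, overlays expression classes onto curated
    protein-complex catalogs to identify 'di-chromatic' complexes, and
    uses backbone geometry of domain-interaction models to call
    mutually exclusive (XOR) versus compatible (AND) interactions at a
    shared hub, with Fisher enrichment over the expression-by-
    compatibility case grid. Includes a synthetic-data generator that
    reproduces the statistical and geometric structure every stage
    assumes, so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    cluster,
    withr,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
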