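Package: placimmune
Title: Targeted Immune Gene Expression Analysis for Placental NanoString Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for targeted immune gene-expression panels
    measured on the NanoString nCounter platform, motivated by placental
    studies of early- and late-onset preeclampsia. Implements sample quality
    control (binding density and control-probe rules), geNorm reference-gene
    selection, negative-control background thresholding and gene filtering,
    housekeeping (content) normalization to a log2 expression matrix,
    per-gene negative-binomial differential expression with a log-linear
    fallback and Benjamini-Hochberg adjustment, marker-based immune cell-type
    scores with pairwise-correlation quality gates, pathway significance and
    per-sample pathway scores, Ward clustering, immunohistochemistry density
    computation, and nonparametric group inference (Kruskal-Wallis with Dunn
    or Nemenyi post-hoc tests, chi-square/Fisher contingency tests). Includes
    a seeded synthetic-data generator that reproduces the statistical
    structure the pipeline assumes, with ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
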