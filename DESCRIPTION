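Package: orgreg
Title: Integrated miRNA-mRNA Targetome Analysis for Diet-Induced
    Obesity-Related Glomerulopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to integrate paired kidney/urine small-RNA and mRNA
    count data from diet-induced obesity studies: a negative-binomial
    study simulator with embedded miRNA-target suppressions and
    histological-lesion labels, simplified negative-binomial differential
    expression with median-of-ratios normalization and Benjamini-Hochberg
    correction, Spearman anti-correlation targetome construction with
    multiplicity classification and hub detection, a label-permutation
    null for lesion-expression association, keyword-based functional
    categorization of target genes, and closed-form qPCR and clearance
    assay calculations, orchestrated as one reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
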