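Package: sclcTyper
Title: Molecular Subtype Calling and Reclassification Screening for SCLC Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the molecular identity of small cell lung
    cancer (SCLC) cell lines from bulk transcriptomic and mutation data.
    Implements dominant-transcription-factor subtype calling (ASCL1,
    NEUROD1, POU2F3, YAP1), a per-subtype mutation prevalence screen with
    subtype-exclusive gene extraction, a correlation-based neuroendocrine
    score against a two-class reference signature, cross-cohort merging
    with quantile normalization, signature-restricted hierarchical
    clustering with reference-anchored cluster labelling, detection and
    exclusion of data-source-driven principal components before gene
    selection, immunohistochemistry H-score computation, and the
    nonparametric statistics (Shapiro-Wilk gating, Mann-Whitney,
    Kruskal-Wallis with Dunn post hoc) used to compare groups. A seeded
    synthetic-cohort generator with planted ground truth supports
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
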