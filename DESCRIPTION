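Package: methylLink
Title: Weight-Loss Methylation Signatures and Their Genetic Coupling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for EPIC-style DNA methylation beta matrices:
    sample QC and nearest-neighbour imputation, beta/M-value transforms,
    paired differential probe discovery with empirical-Bayes variance
    moderation, cross-cohort conservation and gene-direction concordance
    filtering, probe reliability evaluation by one-way random-effects
    intraclass correlation and replicate change rates, elastic-net weighted
    methylation scoring with a graph-Laplacian penalty, coupling of the
    score with copy-number instability, per-chromosome regression,
    mutation rank-sum testing and two-hit gene classification, and
    detection of co-methylated probe blocks under correlation and position
    gap constraints. A synthetic-data module with planted ground truth
    emulates every input so the full pipeline is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
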