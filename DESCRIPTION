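Package: metacohort
Title: Multi-Cohort Gene-Expression Meta-Analysis with Planted-Effect Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-cohort transcriptomic meta-analysis of
    two-group (control versus treated) expression studies. Provides per-cohort
    preprocessing (log2 handling, quantile normalization, probe-to-gene
    collapsing, PCA-based exploratory QC), single-cohort differential expression
    with empirical-Bayes variance moderation and two-tier fold-change/FDR
    thresholds, per-gene cross-cohort random-effects meta-analysis (Hedges'
    adjusted g, DerSimonian-Laird pooling, Cochran's Q, directional Fisher
    sum-of-logs combination with Benjamini-Hochberg FDR), signature selection
    and geometric-mean validation scoring, and hypergeometric pathway
    over-representation with hierarchical top-level-ancestor aggregation.
    Includes a synthetic multi-cohort generator with planted standardized
    effects, between-cohort heterogeneity, and multi-probe redundancy for
    end-to-end validation with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor
Config/testthat/edition: 3
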