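Package: pathscape
Title: Single-Sample Pathway Aberration Profiling and Subgroup Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-sample, per-pathway enrichment and depletion scores
    from ranked gene expression log ratios using a rank-walk AUC statistic
    with permutation-based empirical confidence, combines them into signed
    pathway aberration profiles, discovers tumour subgroups by two-way
    hierarchical clustering (Ward linkage, Euclidean distance), compares
    subgroups across cohorts via aberration frequency features, and tests
    clinical associations (Kaplan-Meier/log-rank survival scans, Fisher's
    exact label enrichment, Wilcoxon rank-sum differential expression).
    Includes gene-set (GMT) ingestion with symbol harmonization and size
    filtering, expression QC (quantile normalization, PCA screening,
    duplicate detection), and a synthetic cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    survival,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    mclust
Config/testthat/edition: 3
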