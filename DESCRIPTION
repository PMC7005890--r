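Package: nanomir
Title: NanoString nCounter miRNA Biomarker Discovery Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of a NanoString nCounter miRNA
    biomarker-discovery workflow for two-group (case/control) panels profiled
    in two blood fractions (a PBMC-like cellular fraction and a plasma
    extracellular-vesicle fraction). Provides RCC lane-file and count-table
    input/output, background thresholding from negative ligation controls
    (geometric mean plus two standard deviations), fraction-specific
    geometric-mean normalization (top-100 endogenous probes or non-human
    spike-in controls), detection and coverage filtering, a single-pass
    two-standard-deviation Chauvenet outlier adjustment, Shapiro-Wilk-branched
    two-group testing (Student's t or Mann-Whitney) with significance tiers
    and asymmetric percent-change reporting, ROC/AUC diagnostics with DeLong
    confidence intervals, Spearman-distance centroid-linkage heatmap ordering,
    cross-fraction Venn bookkeeping, and a negative-binomial synthetic panel
    generator with planted differential expression and injected outliers for
    fully offline end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
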