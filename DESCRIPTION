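Package: cd8sample
Title: Sampling Adequacy of CD8 Immunohistochemistry in Tumor Sections and Simulated Core Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how well limited tissue sampling represents
    CD8+ T-cell infiltration measured by immunohistochemistry. Generates
    synthetic cohorts of tumor blocks (section-level percent-positive tables
    and full spatial slides with cell coordinates and tumor-region polygons),
    estimates patient and section variance components with the intraclass
    correlation coefficient, evaluates one- and two-section classification
    against a cohort-median cutoff by resampling, tessellates slides into
    simulated core-biopsy rectangles with overlap-area filtering, and
    quantifies core-subsampling performance through within-1-SD rates,
    out-of-bag differences, loess variability curves, and ROC analysis
    across candidate percent-positivity cutoffs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
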