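Package: methstab
Title: Longitudinal Stability of Blood DNA Methylation Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the stability of Illumina methylation-array probes
    across two timepoints in multiple cohorts. Computes per-probe mean
    absolute differences (MAD) and their cross-cohort maximum (MMAD),
    two-way absolute-agreement intraclass correlation coefficients with
    F-based confidence intervals, paired t-tests, Pearson correlations and
    pooled standard deviations; detects genotype-driven probes by gap
    segmentation of beta-value distributions; and classifies probes as
    genetically influenced, hyperstable or invariant. Includes a synthetic
    multi-cohort generator (logit-normal subject effects, Hardy-Weinberg
    trimodal genetic probes, detection failures) so the full pipeline is
    testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
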