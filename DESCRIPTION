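Package: omicsurv
Title: Multi-Platform Tumor Cohort Integration with Survival Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis pipeline for multi-platform tumor
    cohorts modelled on glioblastoma multiforme studies. Estimates
    transcript (splice-variant) expression from exon-array intensities by
    least-squares deconvolution against an exon-transcript incidence
    matrix, screens differentially expressed transcripts for survival
    effects with discretized fold-change groups and log-rank tests,
    associates germline SNP genotypes with survival under marker quality
    filters, segments aCGH copy-number profiles by circular binary
    segmentation and calls gains and losses against control-derived
    thresholds, tests whether amplification explains overexpression with a
    permutation weight statistic, summarizes promoter methylation beta
    values and miRNA differential expression, scores siRNA proliferation
    screens with LOESS plate correction and robust z-scores, and fuses all
    per-gene results into a sortable static HTML report. Includes a
    synthetic cohort generator with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    survival,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
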