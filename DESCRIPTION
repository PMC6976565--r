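Package: fmcnv
Title: Dual-Caller Copy-Number Consensus and Survival Analysis for Feline
    Mammary Carcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A windowed read-depth copy-number-variation (CNV) pipeline for
    tumour/normal count data on the feline karyotype: log2 ratio tracks in two
    caller styles (sliding and fixed 2 Mb bins), exact penalized
    piecewise-constant segmentation with minimum segment length (gamma/kmin),
    dual-caller consensus with overlap validation and max-start/min-stop
    boundary refinement, cohort frequency landscapes with common gain/loss
    segments and per-sample CNV burden scores, St. Gallen-style
    immunohistochemical subtyping with gene-level copy-number rescue of
    equivocal HER2, and a survival layer (Kaplan-Meier, Mantel-Cox log-rank,
    forward-stepwise Cox regression, agreement statistics, ROC cutoff
    selection). Includes a synthetic-cohort generator with planted CNV
    segments, overdispersed counts, and hazard-linked outcomes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    survival,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
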