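#' Allred score for hormone-receptor IHC
#'
#' Proportion score (0: 0%; 1: <1%; 2: 1--10%; 3: >10--33%; 4: >33--66%;
#' 5: >66%) plus intensity score (0--3). A total of 3 or more is positive.
#'
#' @param percent_positive Percent positive nuclei in \[0, 100\].
#' @param intensity Staining intensity in \{0, 1, 2, 3\}.
#' @return List with `proportion`, `intensity`, `score` (0--8) and `positive`.
#' @export
allred_score <- function(percent_positive, intensity) {
  if (any(percent_positive < 0 | percent_positive > 100))
    stop("percent_positive out of [0, 100]")
  if (any(!intensity %in% 0:3)) stop("intensity must be 0, 1, 2 or 3")
  p <- percent_positive
  prop <- ifelse(p == 0, 0L,
          ifelse(p < 1, 1L,
          ifelse(p <= 10, 2L,
          ifelse(p <= 33, 3L,
          ifelse(p <= 66, 4L, 5L)))))
  # no stained cells means a negative tumour whatever the nominal intensity
  score <- ifelse(prop == 0L, 0L, prop + as.integer(intensity))
  list(proportion = prop, intensity = as.integer(intensity),
       score = score, positive = score >= 3)
}

#' Ki-67 proliferation class: high iff >= 14%
#' @param percent Percent Ki-67-positive nuclei.
#' @return `"high"` or `"low"` (vectorized).
#' @export
ki67_class <- function(percent) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE)) stop("percent out of range")
  ifelse(percent >= 14, "high", "low")
}

#' CK5/6 basal-marker class: positive iff strictly more than 1% of cells
#' @param percent Percent positive tumour cells.
#' @return `"positive"` or `"negative"` (vectorized).
#' @export
ck56_class <- function(percent) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE)) stop("percent out of range")
  ifelse(percent > 1, "positive", "negative")
}

#' fHER2 status from IHC with gene-level copy-number rescue
#'
#' IHC 3+ is positive and 0/1+ negative regardless of the genomic signal.
#' Equivocal 2+ cases are rescued to positive when the HER2 gene region
#' carries a copy-number gain with log2 ratio strictly above 0.5; a 2+ case
#' whose gene-level log2 is unavailable (masked) is `"equivocal"` and is
#' excluded from subtyping.
#'
#' @param ihc IHC score in \{0, 1, 2, 3\}.
#' @param her2_region_log2 Gene-level log2 from [gene_region_log2()], or `NA`.
#' @return `"positive"`, `"negative"` or `"equivocal"` (vectorized).
#' @export
fher2_status <- function(ihc, her2_region_log2 = NA_real_) {
  if (any(!ihc %in% 0:3)) stop("ihc must be 0, 1, 2 or 3")
  n <- max(length(ihc), length(her2_region_log2))
  ihc <- rep_len(ihc, n); lg <- rep_len(her2_region_log2, n)
  ifelse(ihc == 3, "positive",
  ifelse(ihc <= 1, "negative",
  ifelse(is.na(lg), "equivocal",
  ifelse(lg > 0.5, "positive", "negative"))))
}

#' HER2 gene coding region on the feline genome (FCA E1)
#' @return One-row region data.frame.
#' @export
her2_gene_region <- function() {
  genomic_region("E1", 40780250, 40804241, "neutral")
}

#' Assign the St. Gallen-style molecular subtype
#'
#' Hormone-receptor-positive (ER+ and/or PR+) tumours: fHER2+ gives luminal B
#' fHER2-positive; fHER2- splits on Ki-67 into luminal A (low) vs luminal B
#' fHER2-negative (high). Hormone-receptor-negative tumours: fHER2+ gives the
#' fHER2-positive subtype; fHER2- splits on CK5/6 into basal-like
#' triple-negative (positive) vs normal-like triple-negative (negative).
#' Unresolved fHER2 (equivocal) or missing Ki-67 where it is needed gives
#' `"unclassified"`.
#'
#' @param er_pos,pr_pos Logical hormone-receptor positivity (Allred >= 3).
#' @param fher2 `"positive"`, `"negative"` or `"equivocal"`.
#' @param ck56_pos Logical CK5/6 positivity.
#' @param ki67 `"high"` or `"low"` (may be `NA` when not needed).
#' @return One of `"LA"`, `"LB_fHER2_neg"`, `"LB_fHER2_pos"`, `"fHER2_pos"`,
#'   `"normal_like_TN"`, `"basal_like_TN"`, `"unclassified"` (vectorized).
#' @export
assign_subtype <- function(er_pos, pr_pos, fher2, ck56_pos, ki67) {
  n <- max(length(er_pos), length(pr_pos), length(fher2),
           length(ck56_pos), length(ki67))
  er_pos <- rep_len(er_pos, n); pr_pos <- rep_len(pr_pos, n)
  fher2 <- rep_len(fher2, n); ck56_pos <- rep_len(ck56_pos, n)
  ki67 <- rep_len(ki67, n)
  vapply(seq_len(n), function(i) {
    if (is.na(fher2[i]) || fher2[i] == "equivocal") return("unclassified")
    hr <- isTRUE(er_pos[i]) || isTRUE(pr_pos[i])
    if (hr) {
      if (fher2[i] == "positive") return("LB_fHER2_pos")
      if (is.na(ki67[i])) return("unclassified")
      if (ki67[i] == "high") "LB_fHER2_neg" else "LA"
    } else {
      if (fher2[i] == "positive") return("fHER2_pos")
      if (isTRUE(ck56_pos[i])) "basal_like_TN" else "normal_like_TN"
    }
  }, character(1))
}

#' Classify a clinical table, appending marker calls and subtype
#'
#' Applies [allred_score()], [fher2_status()] (using a per-sample HER2
#' gene-level log2 if supplied), [ck56_class()], [ki67_class()] and
#' [assign_subtype()] to a clinical data.frame.
#'
#' @param clinical data.frame with columns `er_percent`, `er_intensity`,
#'   `pr_percent`, `pr_intensity`, `fher2_ihc`, `ck56_percent`,
#'   `ki67_percent`.
#' @param her2_log2 Optional numeric vector (per sample) of HER2 gene-level
#'   log2 ratios for the 2+ rescue rule.
#' @return The clinical data.frame with `er_pos`, `pr_pos`, `fher2`,
#'   `ck56_pos`, `ki67`, `subtype` columns appended.
#' @export
classify_clinical <- function(clinical, her2_log2 = NA_real_) {
  er <- allred_score(clinical$er_percent, clinical$er_intensity)
  pr <- allred_score(clinical$pr_percent, clinical$pr_intensity)
  clinical$er_pos <- er$positive
  clinical$pr_pos <- pr$positive
  clinical$fher2 <- fher2_status(clinical$fher2_ihc, her2_log2)
  clinical$ck56_pos <- ck56_class(clinical$ck56_percent) == "positive"
  clinical$ki67 <- ki67_class(clinical$ki67_percent)
  clinical$subtype <- assign_subtype(clinical$er_pos, clinical$pr_pos,
                                     clinical$fher2, clinical$ck56_pos,
                                     clinical$ki67)
  clinical
}
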