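---
title: "Dual-caller CNV consensus and survival analysis for feline mammary carcinoma cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-caller CNV consensus and survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmcnv)
```

## The problem

Feline mammary carcinomas (FMCs) are aggressive tumours whose genomic
landscape — chromosome-arm-scale copy-number gains (CNGs) and losses
(CNLs) — carries prognostic information. `fmcnv` implements a complete
analysis chain for windowed tumour/normal read-depth data on the feline
karyotype (chromosomes A1–A3, B1–B4, C1–C2, D1–D4, E1–E3, F1–F2, X):

1. per-sample log2 copy-number-ratio tracks in two caller styles,
2. penalized piecewise-constant segmentation (the γ/kmin smoothing step),
3. dual-caller consensus with overlap validation and boundary refinement,
4. cohort frequency landscapes, common CNG/CNL segments and burden scores,
5. immunohistochemical (St. Gallen-style) molecular subtyping with a
   gene-level HER2 rescue rule, and
6. survival statistics: Kaplan–Meier, Mantel–Cox log-rank, forward-stepwise
   Cox regression, agreement statistics and ROC cutoff selection.

Because suitable cohorts are small and rarely deposited, the package ships a
first-class synthetic-cohort generator whose statistical structure matches
what the analysis assumes. All package-level claims about sensitivity and
specificity are statements about this generator, validated by the test
suite — see *What the simulations do and do not show* below.

## The ratio tracks

Both callers reduce to windowed depth ratios. For tumour counts $t_i$ and a
combined normal reference $n_i$ on window $i$,

$$r_i = \log_2\!\frac{t_i / \sum_j t_j}{\,n_i / \sum_j n_j\,},$$

so tracks are invariant to library size. Caller A uses 2 Mb windows sliding
in 1 Mb steps (twice the bins); caller B uses fixed 2 Mb bins and is
additionally *mode-centred*: the modal log2 value is subtracted so the
dominant — presumed copy-neutral — state sits at zero, which corrects the
baseline of highly aneuploid genomes. The mode is estimated from a
fixed-width histogram (bin width 0.05, a tunable argument) rather than a
KDE so the estimate is deterministic and unit-testable; ties go to the bin
nearest zero. On noisy tracks a single 0.05 bin is too small to identify the
mode reliably, so bin counts are first smoothed with a centred moving sum
whose half-width matches the robust per-window noise SD (estimated from
lag-1 differences); for clean or degenerate tracks this reduces to the raw
histogram. Windows with zero tumour or normal counts are masked rather than
imputed and are excluded from segmentation.

The two normal references are library-size normalized and averaged before
the ratio is formed. The references could instead be used separately with an
intersection of the resulting calls; averaging was chosen because with two
references the per-reference calls are noisier than the pooled track, and
the downstream dual-caller validation already provides a consensus step.

## Segmentation

Each track is smoothed per chromosome into piecewise-constant segments by
the exact global minimizer of

$$\sum_{\text{segments}} \mathrm{SSE} \;+\; \gamma_{\mathrm{eff}}\,(\#\text{segments}-1)$$

subject to every segment containing at least `kmin` windows. The penalized
least-squares formulation is used (rather than recursive binary splitting)
because γ and kmin are its native parameters; the dynamic program is exact,
which lets the tests compare it against exhaustive enumeration of all
breakpoint subsets on short tracks. The DP is $O(n^2)$ per chromosome and
written in C++; at ~2,450 sliding bins genome-wide this is milliseconds per
sample. Ties are broken toward fewer segments, then toward the earliest
last breakpoint, making results deterministic.

γ is interpreted on the *noise-standardized* scale:
$\gamma_{\mathrm{eff}} = \gamma\,\hat\sigma^2$, with $\hat\sigma$ a robust
per-window noise SD (MAD of lag-1 differences divided by $\sqrt2$ — level
shifts from real CNVs affect only a handful of differences, so the estimate
is insensitive to them). This is the convention of the penalized
segmentation literature and is what makes penalties like γ = 10 or 20
meaningful for log2 data, whose raw SSE is orders of magnitude smaller.
Defaults follow the two caller styles: γ = 20, kmin = 20 for the sliding
caller and γ = 10 for the fixed caller, which has half the bins. The fixed
caller's kmin is not pinned down by the convention above; kmin = 5, the
default of the standard penalized-segmentation implementation, is used.
Note that kmin = 20 on ~1 Mb-step sliding bins means the sliding caller
cannot delimit events shorter than about 21 Mb — a real resolution floor of
these parameters that the synthetic cohorts respect (planted events are
chromosome-arm scale, ≥ 22 Mb, matching the ~23 Mb mean of validated FMC
CNVs).

The per-breakpoint penalty (γ per breakpoint, rather than per segment pair)
is the standard reading for this objective and the one implemented.

## Consensus calling

Segments are thresholded into significant regions with strict inequalities:
caller A gain > 0.2 / loss < −0.2; caller B gain > 0.2 / loss < −0.1 (the
mode-centred fixed-bin caller is permitted a looser loss threshold).
Adjacent significant segments of the same sign merge (gap tolerance zero).
A caller-A region is **validated** when more than 80% of its bases are
covered by same-sign caller-B regions; the fraction sums over fragmented
caller-B calls, but boundary refinement uses only the single caller-B region
contributing the largest overlap, because the max-start/min-stop rule is
defined for one pair of intervals:
refined start = max of the two starts, refined stop = min of the two stops.
Sign agreement is required — gains and losses are distinct event classes
throughout — and a refinement that would produce an empty interval drops the
call with a warning instead of emitting an inverted region. The overlap
fraction is one-directional (denominator = the caller-A region length), not
reciprocal; the sensitivity of results to this choice can be probed by
lowering `overlap_min`.

Every validated call carries a runtime containment assertion: the refined
interval must lie inside both source intervals.

## Cohort landscape

Validated calls are rasterized onto the fixed grid (a window is aberrant if
any validated call overlaps it) into a samples × windows gain/loss/neutral
state matrix; conflicting signs at one window in one sample are an error.
Per-window gain and loss frequencies define **common segments**: maximal
runs of contiguous windows, split at chromosome boundaries, with frequency
strictly above 20%. "Frequency-changepoints" are operationalized as the
threshold-crossing boundaries of this track — no separate changepoint
statistic is fitted, because the >20% rule fully determines the segment
ends. A segment's carriers are the samples aberrant (with that sign) in at
least half of its windows; the 50% rule is the package's own choice, made
so that a sample clipped at one edge of a long segment still counts.

Per-sample burden (`cnv_score`) is the percentage of windows aberrant —
overall, gains only, losses only — classed `high` when ≥ the cohort median
of that percentage. Equality goes to `high` (so at least half the cohort is
always high); the alternative reading (strictly greater) changes only
samples exactly at the median.

Gene-level queries (`gene_region_log2`) return the *maximum* segment mean
over segments overlapping the gene interval — a gain anywhere in the gene
body is a gain. This feeds the fHER2 rule below via the feline HER2 coding
region on chromosome E1 (40,780,250–40,804,241 bp).

## Molecular subtyping

Hormone receptors are scored by the standard Allred table (proportion 0–5 +
intensity 0–3; 0% positive cells is negative regardless of nominal
intensity), positive at a total of 3 or more. fHER2 is positive at IHC 3+,
negative at 0/1+ (a high gene-level log2 cannot rescue a 0/1+ case), and an
equivocal 2+ is rescued to positive if the HER2 gene region carries a gain
with log2 strictly above 0.5; a 2+ case with no usable genomic signal stays
equivocal and is excluded from subtyping. CK5/6 is positive strictly above
1% of cells; Ki-67 is high at ≥ 14%. The six-subtype assignment:

| HR (ER and/or PR) | fHER2 | CK5/6 | Ki-67 | subtype |
|---|---|---|---|---|
| + | + | – | – | luminal B fHER2+ |
| + | − | – | low | luminal A |
| + | − | – | high | luminal B fHER2− |
| − | + | – | – | fHER2+ |
| − | − | + | – | basal-like TN |
| − | − | − | – | normal-like TN |

Ki-67 enters only the luminal split and CK5/6 only the triple-negative
split; CK5/6 status does not influence hormone-receptor-positive labels in
this scheme. The table is total: all 32 resolved marker combinations map to
exactly one label (tested exhaustively). HR+ records with Ki-67 unavailable
are `unclassified`.

## Survival statistics

DFS is months from surgery to recurrence (death without recurrence censors
at death); cancer-specific OS is months to tumour-related death (non-tumour
death censors at death); administrative censoring at 24 months. Group
summaries are restricted means (area under the Kaplan–Meier curve truncated
at the largest observed time), the quantity behind "mean ± sem" survival
tables. Log-rank is the k-group Mantel–Cox statistic. The forward-stepwise
Cox procedure adds, at each step, the candidate with the smallest
likelihood-ratio p-value below the entry criterion 0.25, then removes any
included covariate whose removal p-value exceeds the retention criterion
0.1; likelihood-ratio tests are used for both decisions (the score/Wald
variants differ negligibly here and the LR statistic is the more robust
choice); cycling (a covariate entering at p ≈ 0.2 and being removed at the
same p) is terminated by stopping when a model state repeats. Ties between
candidates are broken by covariate name, so the trace is deterministic and
order-independent. Tied event times use the Efron approximation. Candidates
whose fit does not converge (monotone likelihood / complete separation) are
flagged and excluded, and the run continues.

Kaplan–Meier, log-rank and Cox likelihoods are computed by the `survival`
package; the selection loop, Cohen's kappa, percent agreement and the
Youden-J ROC cutoff (ties to the lower cutoff; both reading directions
evaluated and reported) are implemented here. No multiple-testing
correction is applied across univariate tests, matching the analysis style
this pipeline accompanies; p ≤ 0.05 is the significance convention. The
candidate list for the multivariate step is an explicit argument — the
package does not decide which univariate results qualify.

## The synthetic cohort

The generator emulates the data structure the analysis assumes, not any
particular sequencing run:

* **Counts.** Negative-binomial reads per half-window base bin (so one
  realization aggregates coherently onto both caller grids; on the sliding
  grid interior bins contribute to two windows, exactly the double-counting
  a sliding caller performs). `mean_reads_per_window` (default 100 per
  fixed 2 Mb window) sets depth; `dispersion` is the extra-Poisson variance
  fraction, variance = (1 + d)·μ, default d = 0.1 — about 10% more variance
  than Poisson, a realistic figure for megabase-window WGS depth. A planted
  region of log2 amplitude $A$ in a sample of purity $p$ multiplies the
  expectation by $p\,2^A + (1-p)$; default purity 0.8. Two normal
  references are drawn at different library sizes (scale 1 and 1.25) so
  that library-size normalization is actually exercised.
* **Planted events.** The default panel plants five recurrent
  chromosome-arm/whole-chromosome events (E3 gain, B4 gain, B1/D1/X
  losses) with carrier probabilities 0.2–0.42, amplitudes +0.7 (between one
  and two extra copies) and −1.0 (one-copy loss), matching the scale and
  recurrence of validated FMC CNVs. All events span ≥ 22 Mb because the
  sliding caller's kmin = 20 makes ~21 Mb its resolution floor (see
  *Segmentation*).
* **Outcomes.** Recurrence is exponential with hazard
  $h_0 \exp(\sum_j \beta_j c_{ij})$ over carried planted regions
  ($h_0$ = 0.04/month by default; default β: log 4 for the B4 gain, log 2
  for the D1 loss); tumour death follows recurrence by an exponential gap
  (rate 0.25/month); an independent exponential non-tumour death time
  (0.005/month) competes; administrative censoring at 24 months. This is
  exactly the model under which the Cox analysis is well-specified, making
  hazard-ratio recovery a fair end-to-end test.
* **Markers.** IHC values are drawn from subtype-conditional distributions
  centred on rule-consistent values; at `marker_noise = 0` the subtyping
  rules recover every truth subtype exactly, and noise perturbs
  percentages (Gaussian, SD 20·noise) and flips IHC scores with probability
  noise/2. Mitotic counts are Poisson around the Ki-67 level and the three
  grading-system labels derive from them with per-system jitter, giving the
  agreement statistics non-trivial input.

All randomness flows through explicit seeds (`withr::with_seed`; stage
seeds derive from the config seed), so a cohort is byte-identical across
runs and no global RNG state leaks.

### What the simulations do and do not show

The generator reproduces the *statistical skeleton* of a windowed CNV
cohort: overdispersed counts, purity dilution, arm-scale events, hazards
log-linear in carried events, rule-consistent IHC. It deliberately omits
GC/mappability bias, germline CNVs and segmental duplications, FFPE
degradation artefacts, subclonal heterogeneity (one clonal amplitude per
event), inter-sample purity variation beyond a configured vector, and any
spatial correlation of noise. Passing the recovery and specificity tests
therefore shows the pipeline's logic is correct and well-calibrated for
clean arm-scale events — not that these thresholds are optimal for real
FFPE-derived low-coverage data, where bias correction upstream of this
pipeline would matter.

## Numerical and design choices

* Coordinates are 0-based half-open internally; reports use the 1-based
  inclusive Mb style ("B1 1–23 Mb"). Window membership of a region is by
  window midpoint (half-open containment), making window sets unambiguous
  at boundaries.
* Terminal windows shorter than half a window are merged into the previous
  window (fixed grids) or dropped as redundant (sliding grids); at least
  half-window-long tails are kept.
* All significance thresholds are strict inequalities, exactly as stated
  (a segment mean of 0.2 is *not* significant; a frequency of exactly 20%
  does *not* found a common segment; Ki-67 of exactly 14% *is* high).
* The DP's floating-point objective is compared to enumeration at 1e-9;
  tie-breaking differences cannot affect the objective value.
* Degenerate inputs: all-zero normal tracks, empty candidate lists, empty
  strata, single-class ROC outcomes and both-raters-constant kappa raise
  errors or return flagged NA values rather than silently succeeding.

## Problem sizes used in validation

The test suite and the acceptance script run, on one CPU in a few minutes:
200 exhaustive-enumeration segmentation comparisons (tracks ≤ 14 windows);
500 randomized consensus containment cases; planted-event recovery and
null-cohort specificity on 30-sample cohorts over the full feline grid
(~1,224 fixed / ~2,420 sliding windows) across 10 and 5 seeds respectively;
hazard-ratio recovery at n = 400; 50 end-to-end replicates at n = 60 for
the power check; and exhaustive (32-combination) subtype enumeration plus a
100-sample noise-free round trip. These sizes give stable pass/fail
behaviour for the stochastic checks at the stated thresholds.
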