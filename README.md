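# fmcnv — dual-caller CNV consensus and survival analysis for feline mammary carcinoma cohorts

Feline mammary carcinomas (FMCs) carry chromosome-arm-scale copy-number
gains (CNGs) and losses (CNLs) that track with survival. `fmcnv` is an R
package plus analysis workflow for windowed tumour/normal read-depth
cohorts on the feline karyotype (FCA A1–A3, B1–B4, C1–C2, D1–D4, E1–E3,
F1–F2, X). It is aimed at comparative-oncology groups who have window
count matrices (2 Mb bins) for tumours and normal references, a clinical
table with IHC markers and follow-up, and want the full chain from counts
to prognostic statements.

## The method

Per sample, two log2 copy-ratio tracks are formed,
`log2((t_i/Σt) / (n_i/Σn))`, in two caller styles: a sliding-bin track
(2 Mb windows, 1 Mb step; CNV-seq style) and a fixed-bin track (CNVKit
style) that is additionally *mode-centred* so the dominant copy-neutral
level sits at zero. Each track is smoothed by the exact minimizer of

    Σ_segments SSE + γ_eff · (#segments − 1),   |segment| ≥ kmin

(dynamic programming per chromosome, `γ_eff = γ·σ̂²` with σ̂ a robust
per-window noise SD; γ = 20, kmin = 20 for the sliding caller, γ = 10,
kmin = 5 for the fixed caller). Segments are thresholded into significant
regions (sliding: gain > 0.2, loss < −0.2; fixed: gain > 0.2,
loss < −0.1, all strict); a sliding-caller region with > 80% same-sign
coverage by fixed-caller regions is **validated** and refined to
[max(starts), min(stops)). Validated calls pool into a cohort state
matrix, per-window frequency tracks, **common CNG/CNL segments** (maximal
runs with cohort frequency > 20%), and per-sample burden scores (high/low
versus the cohort median percent of aberrant windows). The clinical layer
implements Allred ER/PR scoring (positive ≥ 3), fHER2 (IHC 3+ positive;
2+ rescued by a HER2-region log2 > 0.5), CK5/6 (> 1%), Ki-67 (≥ 14%) and
the six St. Gallen subtypes; the survival layer provides Kaplan–Meier
restricted means, Mantel–Cox log-rank, forward-stepwise Cox (entry 0.25,
retention 0.1, likelihood-ratio tests), Cohen's kappa, percent agreement
and Youden-J ROC cutoffs. A synthetic-cohort generator (negative-binomial
counts, planted arm-scale events, purity dilution, hazards log-linear in
carried events, subtype-conditional IHC) provides ground truth for
end-to-end validation. See `vignettes/cnv-consensus-pipeline.Rmd` for the
model details and design choices.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
33-cat cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_call_cnvs.R
Rscript analysis/03_cohort_landscape.R
Rscript analysis/04_classify_subtypes.R
Rscript analysis/05_survival.R
```

`02_call_cnvs.R` prints:

```
Validated 47 refined CNVs in 29/33 samples (mean length 35.8 Mb).
Per-sample aberrant genome: 2.1% mean (range 0.0-6.1%).
Planted-region recovery at window precision: 47/47 (100%).
```

— every planted event was re-found as a validated CNV with boundaries
within one 2 Mb window. `03_cohort_landscape.R` then recovers the planted
recurrent landscape:

```
Common segments (>20% of cohort): 2 CNG, 2 CNL.
  CNG B4 1-28 Mb  freq 36%  carriers 12
  CNG E3 1-43 Mb  freq 45%  carriers 15
  CNL B1 1-22 Mb  freq 24%  carriers 8
  CNL D1 41-96 Mb  freq 21%  carriers 7
```

and `05_survival.R` fits the stepwise Cox model over the common-segment
carrier indicators (DFS endpoint):

```
     term   coef    hr hr_low hr_high        p
 cng_B4_0  1.730 5.660 2.0800  15.400 0.000691
 cng_E3_0 -1.390 0.249 0.0961   0.644 0.004170
 cnl_B1_0  0.956 2.600 1.0100   6.730 0.048400
```

The B4 gain — simulated with a true hazard ratio of 4 — is selected first
with HR 5.7 (95% CI 2.1–15.4). The E3 and B1 terms have *no* simulated
effect: their retention illustrates how forward-stepwise selection at the
lenient 0.25/0.1 criteria overfits a 33-animal cohort, which is precisely
why multivariate results at this cohort size need external validation.
`04_classify_subtypes.R` reports 85% subtype agreement with the generator
truth at marker noise 0.1 (100% at noise 0), plus grading-system
agreement (EE vs MMEE: 93.9%, κ = 0.89).

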