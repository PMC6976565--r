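#!/usr/bin/env Rscript
# Pool per-sample validated CNVs into the cohort landscape: per-window
# gain/loss frequency track, common CNG/CNL segments (frequency > 20%), and
# per-sample CNV burden scores (high/low vs the cohort median percentage of
# aberrant windows, overall and for gains/losses separately).

library(fmcnv)

res <- readRDS("results/cnv_calls.rds")

freq <- res$freq
write.table(freq, "results/frequency_track.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
common <- res$common
write_common_segments_bed(common, "results/common_segments.bed")
write.table(common[, setdiff(names(common), "windows")],
            "results/common_segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(res$scores, "results/cnv_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Common segments (>20%% of cohort): %d CNG, %d CNL.\n",
            sum(common$variant_type == "CNG"),
            sum(common$variant_type == "CNL")))
for (i in seq_len(nrow(common)))
  cat(sprintf("  %-3s %s  freq %.0f%%  carriers %d\n",
              common$variant_type[i], format_region(common[i, ]),
              100 * common$frequency[i], common$n_carriers[i]))
cat(sprintf("CNV score: %d/%d samples high (>= median %.1f%% aberrant windows).\n",
            sum(res$scores$score_cnv == "high"), nrow(res$scores),
            median(res$scores$pct_aberrant)))
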