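#!/usr/bin/env Rscript
# Pair each phenometric with each BBCH phase per orchard-year and compute
# bias, RMSD and Spearman rank correlation, pooled and stratified by
# hazelnut coverage at the 75% threshold.
library(phenomatch)

metrics <- read.csv("results/phenometrics/phenometrics.csv")
onsets <- read.csv("results/ground/phase_onsets.csv",
                   colClasses = c(bbch = "character"))
meta <- read.csv("results/fixture/pixels.csv")

cmp <- compare_all(metrics, onsets,
                   coverage = meta[c("pixel_id", "coverage")])
dir.create("results/comparison", showWarnings = FALSE, recursive = TRUE)
write.csv(cmp, "results/comparison/comparison.csv", row.names = FALSE)

pooled <- cmp[cmp$stratum == "all", ]
cat(sprintf("%d (metric, phase) cells; %d significant at p < 0.05\n",
            nrow(pooled), sum(pooled$significant_05)))
show <- pooled[order(-abs(pooled$r_s)), ][1:5, ]
cat("strongest rank correlations (pooled):\n")
for (i in seq_len(nrow(show)))
  cat(sprintf("  %-8s vs %-4s  bias %+6.1f d  RMSD %5.1f d  r_s %+.2f  p %.3g\n",
              show$metric[i], show$phase[i], show$bias[i], show$rmsd[i],
              show$r_s[i], show$p_value[i]))
hi <- cmp[cmp$stratum == "coverage_ge_split", ]
lo <- cmp[cmp$stratum == "coverage_lt_split", ]
cat(sprintf("significant cells: %d of %d (coverage >= 75%%) vs %d of %d (< 75%%)\n",
            sum(hi$significant_05), nrow(hi),
            sum(lo$significant_05), nrow(lo)))
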