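#!/usr/bin/env Rscript
# Map weekly survey codes to 3-digit BBCH and reduce them to per-orchard-year
# phase onset dates (first-seen rule; December joins the next season).
library(phenomatch)

loaded <- load_observations("results/fixture/surveys.csv")
onsets <- phase_onsets(loaded$observations, rule = "first-seen")
dir.create("results/ground", showWarnings = FALSE, recursive = TRUE)
write.csv(onsets, "results/ground/phase_onsets.csv", row.names = FALSE)

cat(sprintf("observations: %d mapped, %d unmapped, %d duplicates collapsed\n",
            loaded$report$mapped, loaded$report$unmapped,
            loaded$report$duplicates))
cat(sprintf("%d orchard-year-phase onset rows\n", nrow(onsets)))
for (ph in c("61P", "03VP", "10V", "15V")) {
  s <- summarize_dates(onsets$onset_doy[onsets$bbch == ph], ph)
  cat(sprintf("  BBCH %-4s median onset DOY %4.0f (IQR %.0f-%.0f, n=%d)\n",
              ph, s$p50, s$p25, s$p75, s$n))
}
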