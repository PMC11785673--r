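#!/usr/bin/env Rscript
# Build the synthetic study fixture: 20 orchard pixels on the Black-Sea-like
# parameter ranges, four years of 8-day EVI composites with noise and
# dropouts, matched weekly BBCH surveys, and the generator's truth tables.
library(phenomatch)

out <- "results/fixture"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 42)          # 20 pixels, 2019-2022, defaults
sim <- simulate_series(cfg)
obs <- simulate_surveys(sim)

write_evi_table(sim$series, file.path(out, "evi_composites.csv"))
write.csv(obs, file.path(out, "surveys.csv"), row.names = FALSE)
write.csv(sim$metadata, file.path(out, "pixels.csv"), row.names = FALSE)
write.csv(sim$truth, file.path(out, "truth_params_metrics.csv"),
          row.names = FALSE)
write.csv(sim$phase_truth, file.path(out, "truth_phase_dates.csv"),
          row.names = FALSE)

n_obs <- sum(vapply(sim$series, nrow, integer(1)))
cat(sprintf("fixture: %d pixels x %d years, %d composites, %d survey rows\n",
            cfg$n_pixels, length(cfg$years), n_obs, nrow(obs)))
cat(sprintf("true TRS5 SOS spans DOY %.0f-%.0f (median %.0f)\n",
            min(sim$truth$trs5_sos), max(sim$truth$trs5_sos),
            median(sim$truth$trs5_sos)))
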