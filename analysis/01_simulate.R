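#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# 26 neurotypical controls and 14 FXS participants (8 with NVIQ <= 42, 6 with
# NVIQ > 42), each hearing 18 pseudoword trains of 10 presentations; 99 scalp
# channels, 800-ms epochs at 250 Hz. Habituation profiles: controls suppress
# after P1, the milder FXS phenotype after P3, the lower-functioning subgroup
# not at all, with individual trajectories interpolating along NVIQ.
#
# Writes results/cohort/<participant>.rds and results/meta.csv.

library(rseeg)

seed <- 1L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
saveRDS(cfg, file.path(out, "_config.rds"))
meta <- make_cohort_meta(cfg)
write.csv(meta[, c("participant_id", "group", "nviq", "age", "sex",
                   "subgroup")],
          "results/meta.csv", row.names = FALSE)

for (i in seq_len(nrow(meta))) {
  ep <- generate_participant(cfg, meta[i, ])
  saveRDS(ep, file.path(out, paste0(meta$participant_id[i], ".rds")))
}

cat(sprintf("Simulated %d participants (%d control, %d FXS<=42, %d FXS>42)\n",
            nrow(meta), sum(meta$subgroup == "control"),
            sum(meta$subgroup == "fxs_low"), sum(meta$subgroup == "fxs_high")))
cat(sprintf("Each: %d stimuli x %d presentations x %d channels x %d samples\n",
            cfg$n_stimuli, cfg$n_presentations, cfg$n_channels, cfg$n_samples))
cat("NVIQ ranges by subgroup:\n")
print(tapply(meta$nviq, meta$subgroup, range))
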