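#!/usr/bin/env Rscript
# Stage 3 — data-driven scalp regions of interest.
#
# Separate spatial PCA per diagnostic group on the (participant x
# presentation) by channel matrix of stimulus-averaged energies, Varimax
# rotation of the factors reaching 60% cumulative variance, channels assigned
# by their maximal rotated loading (>= 0.40). The two groups' ROIs are pooled
# into one set used by all later stages.
#
# Writes results/rois.json and per-group loadings CSVs.

library(rseeg)

energy <- read.csv("results/energy_channels.csv")
meta <- read.csv("results/meta.csv")
cfg <- readRDS("results/cohort/_config.rds")

rois <- derive_rois(energy, meta, cfg$montage,
                    cumulative_target = 0.60, loading_threshold = 0.40)
models <- attr(rois, "models")
for (g in names(models)) {
  m <- models[[g]]
  cat(sprintf("%s group: %d factors retained (%.1f%% cumulative variance)\n",
              g, m$n_retained,
              100 * sum(m$variance_explained[seq_len(m$n_retained)])))
  write.csv(data.frame(channel = rownames(m$loadings), round(m$loadings, 4)),
            sprintf("results/loadings_%s.csv", g), row.names = FALSE)
}
print(rois)

jsonlite::write_json(
  lapply(unclass(rois), function(r) r[c("name", "channels", "source_group",
                                        "factor_index")]),
  "results/rois.json", auto_unbox = TRUE, pretty = TRUE)

roi_energy <- rseeg:::aggregate_to_rois(energy, rois)
write.csv(roi_energy, "results/energy_rois.csv", row.names = FALSE)
cat(sprintf("ROI-level energy table: %d rows\n", nrow(roi_energy)))
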