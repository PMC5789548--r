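#!/usr/bin/env Rscript
# Stage 5 — single-trial SVM decoding of the FXS NVIQ subgroups.
#
# Features: within-trial ROI-energy differences E(P1) - E(Pj) and
# E(P2) - E(Pj) (17 per ROI, 119 in total over the pooled 7-ROI set).
# Leave-two-subject-out cross-validation over all 28 balanced 6-vs-6
# bootstrap subsets (216 trials each); per fold an RBF-SVM is trained on the
# 180 trials of ten participants and tested on all 36 trials of the held-out
# pair. Takes a few minutes (about 120k SVM fits).
#
# Writes results/decoding.csv.

library(rseeg)

roi_energy <- read.csv("results/energy_rois.csv")
meta <- read.csv("results/meta.csv")

fm <- build_rs_features(roi_energy, meta)
print(fm)
ids <- lapply(split(fm$participant, fm$label), unique)
plan <- make_fold_plan(ids[[1]], ids[[2]])
print(plan)

res <- run_decoding(fm, plan)
write.csv(as.data.frame(res), "results/decoding.csv", row.names = FALSE)

top <- res[order(-res$mean_da), ][1:10, c("feature", "mean_da", "sem")]
cat("\nTop decoding features (% correct, mean over 28 bootstrap subsets):\n")
print(top, row.names = FALSE, digits = 4)
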