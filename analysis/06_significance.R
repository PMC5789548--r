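#!/usr/bin/env Rscript
# Stage 6 — exact-binomial chance thresholds and significance flags.
#
# The minimum decoding accuracy declared significant is 100 k*/216 where k*
# is the smallest count whose exact binomial upper tail falls below the
# Bonferroni-corrected alpha; the sidedness/multiplicity convention is pinned
# by brute-force calibration against the printed pair 62.96 / 64.35%.
#
# Updates results/decoding.csv with flags; writes results/significance.json.

library(rseeg)

res <- read.csv("results/decoding.csv")

# convention calibrated against the printed 119-feature thresholds, applied
# at this run's feature count
conv <- calibrate_convention(n = 216, m = 119, alphas = c(0.05, 0.01),
                             targets = c(62.96, 64.35))
m_run <- nrow(res)
thr <- vapply(c(p05 = 0.05, p01 = 0.01), function(a)
  as.numeric(binomial_threshold(216, a, m = m_run * conv$multiplier,
                                sided = conv$sided)), 0)
cat(sprintf("Calibrated convention: %s, multiplier %d, %d features\n",
            conv$sided, conv$multiplier, m_run))
cat(sprintf("Chance thresholds: %.2f%% (p < 0.05), %.2f%% (p < 0.01)\n",
            thr["p05"], thr["p01"]))

res <- flag_significant(res, thr)
write.csv(res, "results/decoding.csv", row.names = FALSE)
jsonlite::write_json(list(thresholds = as.list(thr),
                          convention = conv[c("sided", "m_eff", "n")]),
                     "results/significance.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)

sig <- res[res$significance != "ns", ]
sig <- sig[order(-sig$mean_da), ]
cat(sprintf("\n%d of %d features significant after Bonferroni correction\n",
            nrow(sig), nrow(res)))
print(head(sig[, c("feature", "mean_da", "sem", "significance")], 10),
      row.names = FALSE, digits = 4)
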