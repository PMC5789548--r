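# Shared simulation designs for the calibration suites. Montages are reduced
# (energies and habituation profiles do not depend on channel count) so the
# Monte-Carlo loops stay tractable; the methods vignette documents the sizes.

# seven disjoint two-channel sources: full ROI-ladder structure without
# channel overlap between regions
ladder_sim <- function(seed, ...) {
  blocks <- stats::setNames(lapply(1:7, function(k) (2 * k - 1):(2 * k)),
                            c("tl", "fc", "fr", "tr", "oc", "ba", "bt"))
  sim_config(n_channels = 14, topographies = block_topographies(14, blocks),
             seed = seed, ...)
}

# the null generator: flat habituation everywhere, equal gains, and no
# topographic separation between subgroups
null_sim <- function(seed, n_channels = 7, ...) {
  blocks <- stats::setNames(as.list(seq_len(min(7, n_channels))),
                            paste0("s", seq_len(min(7, n_channels))))
  flat <- rep(1.3, 10)
  sim_config(n_channels = n_channels,
             topographies = block_topographies(n_channels, blocks),
             rs_profiles = list(control = flat, fxs_low = flat, fxs_high = flat),
             source_gain = matrix(1, 3, length(blocks),
                                  dimnames = list(c("control", "fxs_low",
                                                    "fxs_high"), NULL)),
             seed = seed, ...)
}

# focused decoding design: one broad source, FXS subgroups with the hard
# median-split profiles (the planted early-presentation difference)
decode_sim <- function(seed, ...) {
  sim_config(n_controls = 1, n_fxs_low = 8, n_fxs_high = 6, n_channels = 48,
             topographies = block_topographies(48, list(src = 1:40)),
             source_gain = rbind(control = 1, fxs_low = 1, fxs_high = 1),
             nviq_blend_scale = Inf, seed = seed, ...)
}

# tiny cohort for shape/contract tests
tiny_sim <- function(seed = 5, ...) {
  sim_config(n_controls = 2, n_fxs_low = 2, n_fxs_high = 2,
             n_stimuli = 4, n_channels = 6,
             topographies = block_topographies(6, list(a = 1:2, b = 3:4, c = 5:6)),
             seed = seed, ...)
}

# ROI-level energies for a config, skipping the filter (synthetic data are
# already band-limited) and using generator-truth ROIs
roi_energy <- function(cfg) {
  run_pipeline(pipeline_config(sim = cfg, filter = FALSE, rereference = FALSE,
                               roi_source = "planted",
                               lmm = FALSE, decode = FALSE))
}
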