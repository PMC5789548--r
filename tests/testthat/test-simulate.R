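test_that("cohort shapes follow the configured design", {
  cfg <- tiny_sim()
  coh <- generate_cohort(cfg)
  expect_length(coh$epochs, 6)
  expect_equal(dim(coh$epochs[[1]]$data), c(4, 10, 6, 200))
  expect_equal(nrow(coh$meta), 6)
  expect_equal(coh$meta$subgroup,
               rep(c("control", "fxs_low", "fxs_high"), each = 2))
  # default design dimensions
  dflt <- sim_config()
  expect_equal(c(dflt$n_stimuli, dflt$n_presentations, dflt$n_channels,
                 dflt$n_samples, dflt$sample_rate), c(18, 10, 99, 200, 250))
  expect_equal(dflt$n_controls + dflt$n_fxs_low + dflt$n_fxs_high, 40)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- tiny_sim(seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$meta, b$meta)
  for (i in seq_along(a$epochs))
    expect_identical(a$epochs[[i]]$data, b$epochs[[i]]$data)
  # per-participant substreams: regenerating one participant reproduces it
  one <- generate_participant(cfg, a$meta[3, ])
  expect_identical(one$data, a$epochs[[3]]$data)
  # a different seed changes the data
  expect_false(identical(generate_cohort(tiny_sim(seed = 78))$epochs[[1]]$data,
                         a$epochs[[1]]$data))
})

test_that("habituation gain profiles encode the three group patterns", {
  cfg <- sim_config()
  expect_equal(rs_profile("fxs_low", 1, cfg), 1.4)
  expect_equal(rs_profile("fxs_low", 7, cfg), 1.4)   # flat: no suppression
  expect_equal(rs_profile("control", 1, cfg), 1.3)
  expect_equal(rs_profile("control", 2, cfg), 1.0)   # step after P1
  expect_equal(rs_profile("fxs_high", 3, cfg), 1.4)
  expect_equal(rs_profile("fxs_high", 4, cfg), 1.0)  # step after P3
  expect_error(rs_profile("unknown", 1, cfg), "unknown group")
  expect_error(rs_profile("control", 11, cfg), "out of range")
})

test_that("NVIQ subgroup labels respect the median-split rule", {
  meta <- make_cohort_meta(sim_config(seed = 3))
  expect_true(all(meta$nviq[meta$subgroup == "fxs_low"] <= 42))
  expect_true(all(meta$nviq[meta$subgroup == "fxs_high"] > 42))
  expect_true(all(meta$group[meta$subgroup == "control"] == "control"))
  expect_true(all(meta$group[meta$subgroup != "control"] == "fxs"))
})

test_that("individual FXS profiles interpolate with NVIQ between the anchors", {
  cfg <- sim_config(seed = 1)
  lo <- participant_profile(cfg, data.frame(group = "fxs", subgroup = "fxs_low",
                                            nviq = 32))
  hi <- participant_profile(cfg, data.frame(group = "fxs", subgroup = "fxs_high",
                                            nviq = 93))
  expect_lt(max(abs(lo - cfg$rs_profiles$fxs_low)), 0.1)
  expect_lt(max(abs(hi - cfg$rs_profiles$fxs_high)), 0.01)
  # hard split when the blend is disabled
  cfg2 <- sim_config(nviq_blend_scale = Inf)
  expect_identical(participant_profile(cfg2, data.frame(group = "fxs",
                                                        subgroup = "fxs_high",
                                                        nviq = 52)),
                   cfg2$rs_profiles$fxs_high)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_stimuli = 0), "counts")
  expect_error(sim_config(rs_profiles = list(control = rep(1, 3),
                                             fxs_low = rep(1, 10),
                                             fxs_high = rep(1, 10))),
               "length")
  # non-orthogonal topographies
  topo <- cbind(c(1, 1, 0, 0) / sqrt(2), c(1, 0, 1, 0) / sqrt(2))
  expect_error(sim_config(n_channels = 4, topographies = topo), "orthogonal")
  # non-unit norm
  expect_error(sim_config(n_channels = 4, topographies = diag(4) * 2),
               "unit")
  expect_error(sim_config(noise_sd = 0, evoked_amplitude = 0,
                          induced_amplitude = 0), "degenerate")
})

test_that("planted topographies are unit-norm and mutually orthogonal", {
  for (n in c(14, 48, 99)) {
    topo <- default_topographies(default_montage(n))
    gram <- crossprod(topo)
    expect_equal(unname(diag(gram)), rep(1, ncol(topo)), tolerance = 1e-10)
    expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  }
})

test_that("first-presentation induced energy exceeds later presentations", {
  # control profile plants a gain step after P1; compare single-epoch induced
  # energies at P1 vs P2 over many participants using the generator's stored
  # noise-free components as oracle
  cfg <- sim_config(n_controls = 200, n_fxs_low = 1, n_fxs_high = 1,
                    n_stimuli = 2, n_channels = 6,
                    topographies = block_topographies(6, list(a = 1:2, b = 3:4,
                                                              c = 5:6)),
                    keep_components = TRUE, artifact_rate = 0, seed = 909)
  meta <- make_cohort_meta(cfg)
  e1 <- e2 <- numeric(0)
  for (i in which(meta$subgroup == "control")) {
    ep <- generate_participant(cfg, meta[i, ])
    ind <- ep$components$induced
    e1 <- c(e1, sum(ind[, 1, , ]^2))
    e2 <- c(e2, sum(ind[, 2, , ]^2))
  }
  expect_lt(t.test(e1, e2, alternative = "greater", paired = TRUE)$p.value,
            0.01)
})

test_that("artifact injection rate matches the configured probability", {
  # >= 10^4 epochs; observed rejection rate within 3 binomial SEs
  cfg <- sim_config(n_controls = 100, n_fxs_low = 1, n_fxs_high = 1,
                    n_stimuli = 10, n_channels = 4, n_samples = 50,
                    topographies = block_topographies(4, list(a = 1:2, b = 3:4)),
                    artifact_rate = 0.05, seed = 411)
  meta <- make_cohort_meta(cfg)
  hits <- total <- 0
  for (i in seq_len(nrow(meta))) {
    ep <- generate_participant(cfg, meta[i, ])
    r <- reject_artifacts(ep, 100)
    hits <- hits + nrow(r$log)
    total <- total + length(ep$mask)
  }
  expect_gte(total, 1e4)
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(hits / total - 0.05), 3 * se)
})
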