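test_that("likelihood-ratio arithmetic is chi2 = 2 * delta logLik", {
  lr <- lrt_stat(-1000, -990, 70)
  expect_equal(lr$chi2, 20)
  expect_equal(lr$df, 70)
  expect_equal(lr$p, pchisq(20, 70, lower.tail = FALSE))
  # non-negative for nested fits even when the larger model is numerically worse
  expect_equal(lrt_stat(-990, -990.001, 3)$chi2, 0)
})

test_that("summary contrast t matches the closed form", {
  se <- 16 / sqrt(26)
  expect_equal(summary_contrast_t(213.2, 192.2, se),
               (213.2 - 192.2) / sqrt(2 * se^2), tolerance = 1e-9)
  expect_equal(summary_contrast_t(1, 0, 2, 1.5), 1 / sqrt(4 + 2.25))
})

test_that("mixed model fits converge and AIC follows its definition", {
  b <- roi_energy(ladder_sim(55))
  d <- lmm_data(b$roi_table, b$meta)
  f <- fit_mixed(d, energy ~ rep_f * roi, covariance = "ar1")
  expect_true(f$converged)
  expect_true(f$random_slope)
  expect_equal(f$AIC, -2 * f$logLik + 2 * f$k, tolerance = 1e-8)
  expect_true("rep_f" %in% rownames(f$fixed_effect_tests))

  # AIC ordering is invariant to adding a constant to the outcome
  d2 <- d; d2$energy <- d2$energy + 1000
  f_id <- fit_mixed(d, energy ~ rep_f * roi, covariance = "identity")
  f2 <- fit_mixed(d2, energy ~ rep_f * roi, covariance = "ar1")
  f2_id <- fit_mixed(d2, energy ~ rep_f * roi, covariance = "identity")
  expect_equal(f$AIC - f_id$AIC, f2$AIC - f2_id$AIC, tolerance = 1e-3)
})

test_that("AR(1) covariance is preferred on serially correlated residuals", {
  # synthetic ROI-level table with AR(1) (rho = 0.5) within-cell residuals
  set.seed(424)
  wins <- 0
  for (rep in 1:20) {
    d <- expand.grid(presentation = 1:10, region = paste0("R", 1:3),
                     participant_id = sprintf("S%02d", 1:20))
    ar <- as.vector(replicate(3 * 20, as.numeric(
      arima.sim(list(ar = 0.5), 10, sd = 5))))
    d$energy <- 200 + ar
    d$stimulus <- 1L
    meta <- data.frame(participant_id = sprintf("S%02d", 1:20),
                       group = rep(c("control", "fxs"), 10),
                       nviq = 70, age = 20)
    dd <- lmm_data(d, meta)
    a <- fit_mixed(dd, energy ~ rep_f * roi, covariance = "ar1")
    i <- fit_mixed(dd, energy ~ rep_f * roi, covariance = "identity")
    wins <- wins + (a$AIC < i$AIC)
  }
  expect_gte(wins / 20, 0.9)
})

test_that("the ladder runs the stated step order and sweeps covariances", {
  b <- roi_energy(ladder_sim(56))
  suppressWarnings(lad <- run_ladder(b$roi_table, b$meta))
  expect_equal(lad$steps$predictor, c("group", "nviq", "age"))
  expect_equal(lad$steps$accepted, lad$steps$p < 0.05)
  expect_true(all(lad$steps$chi2 >= 0))
  # group model adds 70 fixed parameters, the NVIQ block 20
  expect_equal(lad$steps$df[1:2], c(70, 20))
  expect_named(lad$aic_by_covariance, c("identity", "cs", "ar1"))
  expect_equal(lad$covariance_selected,
               names(which.min(lad$aic_by_covariance)))
  # rerunning on the same table reproduces the decisions exactly
  suppressWarnings(lad2 <- run_ladder(b$roi_table, b$meta))
  expect_equal(lad$steps, lad2$steps, tolerance = 1e-10)
})

test_that("post hoc contrasts are gated, Bonferroni-corrected and complete", {
  b <- roi_energy(ladder_sim(57))
  meta <- b$meta
  dc <- lmm_data(b$roi_table[b$roi_table$subgroup == "control", ], meta)
  f <- fit_mixed(dc, energy ~ rep_f * roi, covariance = "ar1")
  expect_lt(f$fixed_effect_tests["rep_f", "p-value"], 0.05)
  ph <- posthoc_pairwise(f)
  expect_equal(nrow(ph), 45)
  # corrected p >= uncorrected and capped at 1
  emm <- suppressMessages(emmeans::emmeans(f$model, "rep_f", data = f$data))
  raw <- as.data.frame(suppressMessages(
    emmeans::contrast(emm, "pairwise", adjust = "none")))
  expect_true(all(ph$p_bonferroni >= raw$p.value - 1e-12))
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(ph$p_bonferroni, pmin(raw$p.value * 45, 1), tolerance = 1e-9)
  # control profile: the P1 vs P2 drop is the leading contrast
  expect_lt(ph$p_bonferroni[ph$pair == "1 - 2"], 0.05)
  expect_gt(ph$estimate[ph$pair == "1 - 2"], 0)

  # refused when the repetition main effect is absent
  null_b <- roi_energy(null_sim(58))
  dn <- lmm_data(null_b$roi_table, null_b$meta)
  fn <- fit_mixed(dn, energy ~ rep_f * roi, covariance = "ar1")
  if (fn$fixed_effect_tests["rep_f", "p-value"] >= 0.05)
    expect_error(posthoc_pairwise(fn), "refused")
})

test_that("the projected GLS fit tests repetition terms on the identifiable subspace", {
  b <- roi_energy(ladder_sim(58))
  d <- lmm_data(b$roi_table, b$meta)
  f <- fit_mixed(d, energy ~ rep_f * roi, covariance = "unstructured")
  expect_s3_class(f, "rs_lmm")
  # constant-in-presentation terms vanish under the projection
  expect_false("roi" %in% rownames(f$fixed_effect_tests))
  expect_true(all(c("rep_f", "rep_f:roi") %in% rownames(f$fixed_effect_tests)))
  # the planted habituation step is detected
  expect_lt(f$fixed_effect_tests["rep_f", "p-value"], 0.01)
  # residual df reflect the projected dimension (9 per complete cell)
  expect_lte(f$fixed_effect_tests["rep_f", "denDF"],
             9 * nlevels(interaction(d$participant_id, d$roi, drop = TRUE)))
  expect_true(is.finite(f$AIC))
})

test_that("a degenerate random-effects structure falls back to gls", {
  set.seed(9)
  d <- expand.grid(presentation = 1:10, region = "R1",
                   participant_id = sprintf("S%02d", 1:4))
  d$energy <- rnorm(40)
  d$stimulus <- 1L
  meta <- data.frame(participant_id = unique(d$participant_id),
                     group = c("control", "control", "fxs", "fxs"),
                     nviq = 70, age = 20)
  dd <- lmm_data(d, meta)
  f <- fit_mixed(dd, energy ~ rep_f, covariance = "identity")
  expect_s3_class(f, "rs_lmm")
  expect_true(is.finite(f$logLik))
})
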