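# small deterministic feature setup: n_a + n_b participants, t trials each
toy_labels <- function(n_a = 8, n_b = 6, t = 18) {
  list(participant = rep(c(sprintf("L%d", 1:n_a), sprintf("H%d", 1:n_b)),
                         each = t),
       label = factor(rep(c("fxs_low", "fxs_high"), c(n_a * t, n_b * t)),
                      levels = c("fxs_low", "fxs_high")))
}

test_that("the fold plan enumerates 28 balanced subsets of disjoint folds", {
  plan <- make_fold_plan(sprintf("L%d", 1:8), sprintf("H%d", 1:6))
  expect_length(plan$subsets, choose(8, 6))      # 28 bootstrap subsets
  expect_equal(nrow(plan$folds), 28 * 36)        # 36 cross-class pairs each
  tl <- toy_labels()
  idx <- rseeg:::plan_row_indices(plan, tl$participant)
  for (ri in idx) {
    expect_length(ri$train, 180)                 # 10 participants x 18 trials
    expect_length(ri$test, 36)                   # 2 participants x 18 trials
    expect_length(intersect(tl$participant[ri$train],
                            tl$participant[ri$test]), 0)
  }
  # every balanced subset contains 216 samples
  for (k in seq_along(plan$subsets)) {
    n_sub <- sum(tl$participant %in% c(plan$subsets[[k]], plan$ids_b))
    expect_equal(n_sub, 216)
  }
  expect_error(make_fold_plan("a", c("b", "c")), "at least 2")
  # disjoint pairing: one fold per participant pair rotation
  pd <- make_fold_plan(sprintf("L%d", 1:8), sprintf("H%d", 1:6),
                       pairing = "disjoint")
  expect_equal(nrow(pd$folds), 28 * 6)
})

test_that("feature matrices have 17 features per ROI and one row per trial", {
  cfg <- tiny_sim(artifact_rate = 0, seed = 41)
  b <- roi_energy(cfg)
  fm <- build_rs_features(b$roi_table, b$meta)
  expect_equal(nrow(fm$x), 4 * 4)                # 4 FXS participants x 4 stimuli
  expect_equal(ncol(fm$x), 17 * 3)               # 17 pairs per region
  expect_equal(as.vector(table(fm$label)), c(2 * 4, 2 * 4))
  expect_true(all(grepl("^[a-c] [12]-(10|[2-9])$", colnames(fm$x))))
  # features subtract within-trial energies: the table consistency check
  et <- b$roi_table[b$roi_table$participant_id == "P03" &
                      b$roi_table$stimulus == 1 & b$roi_table$region == "a", ]
  expected <- et$energy[et$presentation == 1] - et$energy[et$presentation == 2]
  row <- which(fm$participant == "P03" & fm$stimulus == 1)
  expect_equal(unname(fm$x[row, "a 1-2"]), expected)

  # ROI energies 213.2 at P1 and 192.2 at P2 -> feature "1-2" = 21.0
  rt <- expand.grid(presentation = 1:10, stimulus = 1, region = "FR",
                    participant_id = c("F1", "F2"), stringsAsFactors = FALSE)
  rt$subgroup <- ifelse(rt$participant_id == "F1", "fxs_low", "fxs_high")
  rt$energy <- 200
  rt$energy[rt$presentation == 1] <- 213.2
  rt$energy[rt$presentation == 2] <- 192.2
  meta2 <- data.frame(participant_id = c("F1", "F2"), group = "fxs",
                      subgroup = c("fxs_low", "fxs_high"))
  fm2 <- build_rs_features(rt, meta2)
  expect_equal(unname(fm2$x[1, "FR 1-2"]), 21, tolerance = 1e-9)

  # constant energies give all-zero features
  flat <- b$roi_table
  flat$energy <- 5
  fm0 <- build_rs_features(flat, b$meta)
  expect_true(all(fm0$x == 0))
})

test_that("rejected constituent presentations yield NA features that are dropped", {
  cfg <- tiny_sim(artifact_rate = 0, seed = 42)
  b <- roi_energy(cfg)
  rt <- b$roi_table[!(b$roi_table$participant_id == "P03" &
                        b$roi_table$stimulus == 2 &
                        b$roi_table$presentation == 4), ]
  fm <- build_rs_features(rt, b$meta)
  row <- which(fm$participant == "P03" & fm$stimulus == 2)
  expect_true(is.na(fm$x[row, "a 1-4"]))
  expect_true(is.na(fm$x[row, "a 2-4"]))
  expect_false(is.na(fm$x[row, "a 1-5"]))
  ids <- lapply(split(fm$participant, fm$label), unique)
  plan <- make_fold_plan(ids[[1]], ids[[2]])
  r <- decode_feature(fm$x[, "a 1-4"], fm$label, fm$participant, plan)
  expect_true(is.finite(r$mean_da))
})

test_that("a perfectly separated feature decodes at 100%", {
  tl <- toy_labels()
  x <- ifelse(tl$label == "fxs_low", -2, 2) + rnorm(length(tl$label), 0, 0.01)
  plan <- make_fold_plan(unique(tl$participant[tl$label == "fxs_low"]),
                         unique(tl$participant[tl$label == "fxs_high"]))
  r <- decode_feature(x, tl$label, tl$participant, plan)
  expect_equal(r$mean_da, 100)
  expect_equal(r$sem, 0)
})

test_that("an all-zero feature decodes at the balanced-class baseline", {
  tl <- toy_labels()
  plan <- make_fold_plan(unique(tl$participant[tl$label == "fxs_low"]),
                         unique(tl$participant[tl$label == "fxs_high"]))
  r <- decode_feature(rep(0, length(tl$label)), tl$label, tl$participant, plan)
  expect_equal(r$mean_da, 50)
})

test_that("decoding is invariant to affine transforms of a feature", {
  set.seed(43)
  tl <- toy_labels()
  x <- rnorm(length(tl$label)) + ifelse(tl$label == "fxs_low", 0, 0.8)
  plan <- make_fold_plan(unique(tl$participant[tl$label == "fxs_low"]),
                         unique(tl$participant[tl$label == "fxs_high"]))
  r1 <- decode_feature(x, tl$label, tl$participant, plan)
  r2 <- decode_feature(3.7 * x - 11, tl$label, tl$participant, plan)
  expect_equal(r1$mean_da, r2$mean_da, tolerance = 1e-9)
  expect_equal(r1$subset_da, r2$subset_da, tolerance = 1e-9)
})

test_that("permuted labels decode at chance", {
  set.seed(44)
  tl <- toy_labels()
  x <- rnorm(length(tl$label)) + ifelse(tl$label == "fxs_low", 0, 1)
  plan <- make_fold_plan(unique(tl$participant[tl$label == "fxs_low"]),
                         unique(tl$participant[tl$label == "fxs_high"]),
                         pairing = "disjoint")
  das <- replicate(20, {
    # permute participants' class assignment (6 of 14 relabelled high)
    ids <- unique(tl$participant)
    hi <- sample(ids, 6)
    y <- factor(ifelse(tl$participant %in% hi, "fxs_high", "fxs_low"),
                levels = c("fxs_low", "fxs_high"))
    p2 <- make_fold_plan(setdiff(ids, hi), hi, pairing = "disjoint")
    decode_feature(x, y, tl$participant, p2)$mean_da
  })
  band <- 100 * qbinom(c(0.025, 0.975), 216, 0.5) / 216
  expect_gt(mean(das), band[1])
  expect_lt(mean(das), band[2])
})

test_that("a mean shift of two SDs is decodable above the chance threshold", {
  # two-Gaussian feature, unit variance, shift 2.0, 6 + 8 participants
  passes <- 0
  n_sim <- 50
  for (s in seq_len(n_sim)) {
    set.seed(5000 + s)
    tl <- toy_labels()
    x <- rnorm(length(tl$label)) + ifelse(tl$label == "fxs_low", 0, 2)
    plan <- make_fold_plan(unique(tl$participant[tl$label == "fxs_low"]),
                           unique(tl$participant[tl$label == "fxs_high"]),
                           pairing = "disjoint")
    da <- decode_feature(x, tl$label, tl$participant, plan)$mean_da
    passes <- passes + (da > 62.96)
  }
  expect_gte(passes / n_sim, 0.8)
})

test_that("run_decoding aggregates per-feature results in column order", {
  cfg <- tiny_sim(artifact_rate = 0, seed = 45)
  b <- roi_energy(cfg)
  fm <- build_rs_features(b$roi_table, b$meta)
  res <- run_decoding(fm, columns = c("a 1-2", "b 2-4"))
  expect_equal(res$feature, c("a 1-2", "b 2-4"))
  expect_true(all(res$mean_da >= 0 & res$mean_da <= 100))
  # two FXS participants per class -> a single balanced subset
  expect_equal(dim(attr(res, "subset_da")), c(2, 1))
})
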