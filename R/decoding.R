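#' Single-trial repetition-suppression feature matrix
#'
#' One row per FXS trial (participant x pseudoword stimulus); per ROI the
#' features are the within-trial energy differences E(P1) - E(Pj), j = 2..10,
#' followed by E(P2) - E(Pj), j = 3..10 — 17 features per ROI. Column labels
#' are "<ROI> <i>-<j>". Trials whose constituent presentation was rejected
#' carry NA in the affected features and are dropped per feature at decoding
#' time.
#'
#' @param energy ROI-level energy table.
#' @param meta cohort metadata; only `group == "fxs"` rows are used.
#' @return object of class `rs_feature_matrix`: list with `x` (trials x
#'   features), `label` (factor fxs_low/fxs_high), `participant` (per row),
#'   `stimulus`, and `feature_info` (roi, i, j per column).
#' @export
build_rs_features <- function(energy, meta) {
  ids <- meta$participant_id[meta$group == "fxs"]
  if (length(ids) == 0) stop("no FXS participants in metadata")
  dt <- data.table::as.data.table(energy[energy$participant_id %in% ids, ])
  rois <- unique(dt$region)
  P <- max(dt$presentation)
  pairs <- rbind(data.frame(i = 1, j = seq(2, P)),
                 data.frame(i = 2, j = seq(3, P)))
  wide <- data.table::dcast(dt, participant_id + stimulus + region ~ presentation,
                            value.var = "energy")
  pcols <- as.character(seq_len(P))
  missing_p <- setdiff(pcols, names(wide))
  for (mp in missing_p) wide[[mp]] <- NA_real_
  trials <- unique(wide[, c("participant_id", "stimulus")])
  data.table::setkey(wide, participant_id, stimulus, region)
  X <- matrix(NA_real_, nrow(trials), nrow(pairs) * length(rois))
  labels <- character(nrow(pairs) * length(rois))
  info <- data.frame()
  col <- 0
  for (r in rois) {
    w <- wide[wide$region == r, ]
    w <- w[match(paste(trials$participant_id, trials$stimulus),
                 paste(w$participant_id, w$stimulus)), ]
    em <- as.matrix(w[, pcols, with = FALSE])
    for (q in seq_len(nrow(pairs))) {
      col <- col + 1
      X[, col] <- em[, pairs$i[q]] - em[, pairs$j[q]]
      labels[col] <- sprintf("%s %d-%d", r, pairs$i[q], pairs$j[q])
    }
    info <- rbind(info, data.frame(roi = r, i = pairs$i, j = pairs$j))
  }
  colnames(X) <- labels
  sub <- meta$subgroup[match(trials$participant_id, meta$participant_id)]
  out <- list(x = X,
              label = factor(sub, levels = c("fxs_low", "fxs_high")),
              participant = as.character(trials$participant_id),
              stimulus = trials$stimulus,
              feature_info = info)
  class(out) <- "rs_feature_matrix"
  out
}

#' @export
print.rs_feature_matrix <- function(x, ...) {
  cat(sprintf("<rs_feature_matrix: %d trials x %d features, classes %s>\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", levels(x$label),
                            tabulate(as.integer(unclass(x$label)), nlevels(x$label))),
                    collapse = ", ")))
  invisible(x)
}

#' Leave-two-subject-out, bootstrap-balanced fold plan
#'
#' Enumerates every subset of the larger class with the size of the smaller
#' class (bootstrap class balancing; C(8,6) = 28 for the canonical 8-vs-6
#' split). Within each balanced subset, every cross-class participant pair
#' forms one fold: the pair's trials are the test set and the remaining
#' participants' trials the training set, so no participant ever appears on
#' both sides.
#'
#' @param ids_a participant ids of the larger class.
#' @param ids_b participant ids of the smaller class.
#' @param pairing `"exhaustive"` (every cross-class pair, the default) or
#'   `"disjoint"` (one rotation pairing each participant once per subset —
#'   same per-subset evaluation count, fewer model fits; used in
#'   calibration studies).
#' @return object of class `fold_plan`: list with `subsets` (list of balanced
#'   participant sets of class a) and `folds`, a data.frame (subset, test_a,
#'   test_b).
#' @export
make_fold_plan <- function(ids_a, ids_b,
                           pairing = c("exhaustive", "disjoint")) {
  pairing <- match.arg(pairing)
  if (length(ids_a) < length(ids_b)) { tmp <- ids_a; ids_a <- ids_b; ids_b <- tmp }
  if (length(ids_b) < 2) stop("each class needs at least 2 participants")
  subsets <- utils::combn(ids_a, length(ids_b), simplify = FALSE)
  folds <- do.call(rbind, lapply(seq_along(subsets), function(k) {
    if (pairing == "exhaustive") {
      expand.grid(subset = k, test_a = subsets[[k]], test_b = ids_b,
                  stringsAsFactors = FALSE)
    } else {
      data.frame(subset = k, test_a = subsets[[k]], test_b = ids_b,
                 stringsAsFactors = FALSE)
    }
  }))
  out <- list(subsets = subsets, ids_a = ids_a, ids_b = ids_b, folds = folds)
  class(out) <- "fold_plan"
  out
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: %d balanced subsets x %d folds each (classes %d vs %d)>\n",
              length(x$subsets), nrow(x$folds) / length(x$subsets),
              length(x$ids_a), length(x$ids_b)))
  invisible(x)
}

# Resolve the plan against the rows of a feature matrix once, so the row
# indices are shared by all per-feature decodings.
plan_row_indices <- function(plan, participant) {
  lapply(seq_len(nrow(plan$folds)), function(f) {
    k <- plan$folds$subset[f]
    test_ids <- c(plan$folds$test_a[f], plan$folds$test_b[f])
    active <- c(setdiff(plan$subsets[[k]], plan$folds$test_a[f]),
                setdiff(plan$ids_b, plan$folds$test_b[f]))
    list(subset = k,
         train = which(participant %in% active),
         test = which(participant %in% test_ids))
  })
}

#' Decode one feature under a fold plan
#'
#' Per fold: z-score using training statistics only, fit an RBF-kernel SVM
#' (C = 1, gamma = 1 on the standardized scalar feature) on the training
#' trials, and score the held-out pair's trials. Per-subset decoding accuracy
#' (DA) is the mean fold accuracy; the reported `mean_da` averages the
#' subsets and `sem` is their SD / sqrt(n_subsets) — dispersion across the
#' bootstrap repetitions. Trials with a missing value (artifact-rejected
#' constituent presentation) are dropped from both sides; folds whose
#' training set degenerates to a single class are skipped and counted.
#'
#' @param x numeric feature vector (one column of the feature matrix).
#' @param y class labels (factor, 2 levels).
#' @param participant participant id per trial.
#' @param plan a `fold_plan`.
#' @param cost,gamma SVM hyperparameters.
#' @param row_idx precomputed [plan_row_indices()] (optional, for speed).
#' @return list: mean_da (%), sem (%), subset_da, n_skipped_folds.
#' @export
decode_feature <- function(x, y, participant, plan, cost = 1, gamma = 1,
                           row_idx = NULL) {
  if (is.null(row_idx)) row_idx <- plan_row_indices(plan, participant)
  nsub <- length(plan$subsets)
  acc <- matrix(NA_real_, nsub, nrow(plan$folds) / nsub)
  foldpos <- integer(nsub)
  skipped <- 0
  for (f in seq_along(row_idx)) {
    ri <- row_idx[[f]]
    tr <- ri$train[!is.na(x[ri$train])]
    te <- ri$test[!is.na(x[ri$test])]
    k <- ri$subset
    foldpos[k] <- foldpos[k] + 1
    if (length(te) == 0 || length(unique(y[tr])) < 2) { skipped <- skipped + 1; next }
    mu <- mean(x[tr]); sdv <- stats::sd(x[tr]); if (!is.finite(sdv) || sdv == 0) sdv <- 1
    xtr <- matrix((x[tr] - mu) / sdv)
    xte <- matrix((x[te] - mu) / sdv)
    fit <- e1071::svm(xtr, factor(y[tr]), kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, xte)
    acc[k, foldpos[k]] <- mean(as.character(pred) == as.character(y[te]))
  }
  subset_da <- 100 * rowMeans(acc, na.rm = TRUE)
  list(mean_da = mean(subset_da), sem = stats::sd(subset_da) / sqrt(nsub),
       subset_da = subset_da, n_skipped_folds = skipped)
}

#' Decode every feature of a feature matrix
#'
#' @param fm an `rs_feature_matrix`.
#' @param plan a `fold_plan` (defaults to the full plan over the matrix's
#'   participants by class).
#' @param cost,gamma SVM hyperparameters.
#' @param columns optional subset of feature columns (names or indices).
#' @return object of class `decoding_result`: data.frame with feature, roi,
#'   i, j, mean_da, sem, n_skipped_folds; per-subset DA matrix in attribute
#'   `"subset_da"`.
#' @export
run_decoding <- function(fm, plan = NULL, cost = 1, gamma = 1, columns = NULL) {
  if (is.null(plan)) {
    ids <- lapply(split(fm$participant, fm$label), unique)
    plan <- make_fold_plan(ids[[1]], ids[[2]])
  }
  cols <- if (is.null(columns)) seq_len(ncol(fm$x)) else columns
  if (is.character(cols)) cols <- match(cols, colnames(fm$x))
  row_idx <- plan_row_indices(plan, fm$participant)
  res <- lapply(cols, function(jc)
    decode_feature(fm$x[, jc], fm$label, fm$participant, plan,
                   cost = cost, gamma = gamma, row_idx = row_idx))
  out <- data.frame(
    feature = colnames(fm$x)[cols],
    fm$feature_info[cols, , drop = FALSE],
    mean_da = vapply(res, `[[`, 0, "mean_da"),
    sem = vapply(res, `[[`, 0, "sem"),
    n_skipped_folds = vapply(res, function(r) as.integer(r$n_skipped_folds), 0L),
    row.names = NULL
  )
  attr(out, "subset_da") <- do.call(rbind, lapply(res, `[[`, "subset_da"))
  class(out) <- c("decoding_result", "data.frame")
  out
}
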