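#' Observation matrix for spatial PCA
#'
#' One row per (participant, presentation), one column per channel; entries
#' are normalized energies averaged over the pseudoword stimuli. This is the
#' observations-by-electrodes layout used for group-wise spatial factor
#' analysis.
#'
#' @param energy channel-level energy table from [energy_table()].
#' @param meta cohort metadata.
#' @param group `"control"` or `"fxs"` (diagnostic group, both NVIQ subgroups).
#' @return numeric matrix (n_group * n_presentations) x n_channels.
#' @export
build_observation_matrix <- function(energy, meta, group) {
  ids <- meta$participant_id[meta$group == group]
  if (length(ids) == 0) stop("no participants in group ", group)
  dt <- data.table::as.data.table(energy[energy$participant_id %in% ids, ])
  if (nrow(dt) == 0) stop("no energy rows for group ", group)
  agg <- dt[, list(energy = mean(energy)),
            by = c("participant_id", "presentation", "region")]
  wide <- data.table::dcast(agg, participant_id + presentation ~ region,
                            value.var = "energy")
  channels <- setdiff(names(wide), c("participant_id", "presentation"))
  m <- as.matrix(wide[, channels, with = FALSE])
  rownames(m) <- paste(wide$participant_id, wide$presentation, sep = ":")
  # restore montage channel order (dcast sorts lexicographically)
  ord <- order(as.integer(sub("^E", "", channels)))
  if (!anyNA(ord)) m <- m[, ord, drop = FALSE]
  m
}

#' Tucker congruence coefficient
#'
#' @param x,y loading vectors.
#' @return sum(xy) / sqrt(sum(x^2) sum(y^2)).
#' @export
tucker_congruence <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

#' Spatial PCA with Varimax rotation
#'
#' Principal components of the column-standardized (correlation-matrix)
#' observation matrix. The smallest leading set of components whose cumulative
#' variance reaches `cumulative_target` is retained and Varimax-rotated
#' (Kaiser normalization, as in the classic SPSS workflow). Rotation is
#' orthogonal, so per-channel communalities and the total retained variance
#' are preserved.
#'
#' @param x observation matrix from [build_observation_matrix()].
#' @param cumulative_target proportion of variance to retain (default 0.60).
#' @param group optional group label carried in the result.
#' @return object of class `spatial_factor_model`: rotated `loadings`
#'   (channels x factors, correlation metric), `unrotated` loadings,
#'   `variance_explained` (per-component proportions, all components),
#'   `n_retained`, `cumulative_target`, `group`.
#' @export
spatial_pca <- function(x, cumulative_target = 0.60, group = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance channel(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  prop <- eg$values / ncol(x)
  n_retained <- which(cumsum(prop) >= cumulative_target)[1]
  if (is.na(n_retained)) n_retained <- ncol(x)
  # factor-analysis metric: loading = eigenvector * sqrt(eigenvalue)
  A <- eg$vectors[, seq_len(n_retained), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(n_retained)]), n_retained)
  rot <- if (n_retained > 1) {
    v <- stats::varimax(A, normalize = TRUE)
    A %*% v$rotmat
  } else A
  # orient each factor so its dominant loading is positive
  flip <- apply(rot, 2, function(l) sign(l[which.max(abs(l))]))
  rot <- sweep(rot, 2, flip, `*`)
  rownames(rot) <- rownames(A) <- colnames(x)
  out <- list(loadings = rot, unrotated = A,
              variance_explained = prop,
              rotated_variance = colSums(rot^2) / ncol(x),
              n_retained = n_retained,
              cumulative_target = cumulative_target,
              group = group)
  class(out) <- "spatial_factor_model"
  out
}

#' @export
print.spatial_factor_model <- function(x, ...) {
  cat(sprintf("<spatial_factor_model%s: %d factors retained (cumulative %.1f%% >= %.0f%% target)>\n",
              if (is.null(x$group)) "" else paste0(" ", x$group),
              x$n_retained, 100 * sum(x$variance_explained[seq_len(x$n_retained)]),
              100 * x$cumulative_target))
  invisible(x)
}

#' Convert rotated factors to channel ROIs
#'
#' Each channel is assigned to the factor on which its absolute rotated
#' loading is maximal, provided that loading reaches `loading_threshold`
#' (boundary kept). Factors left with no channel are dropped. ROIs are named
#' after the spatial centroid of their channels.
#'
#' @param model a `spatial_factor_model`.
#' @param montage montage data.frame (for naming).
#' @param loading_threshold salient-loading cutoff (default 0.40).
#' @return object of class `roi_set`: list of
#'   list(name, channels, source_group, factor_index).
#' @export
factors_to_rois <- function(model, montage, loading_threshold = 0.40) {
  L <- abs(model$loadings)
  best <- max.col(L, ties.method = "first")
  bestload <- L[cbind(seq_len(nrow(L)), best)]
  assigned <- bestload >= loading_threshold
  if (!any(assigned)) stop("empty ROI set: no loading reaches the threshold")
  rois <- list()
  for (f in sort(unique(best[assigned]))) {
    ch <- rownames(L)[assigned & best == f]
    if (length(ch) == 0) next
    rois[[length(rois) + 1]] <- list(
      name = roi_name_from_centroid(ch, montage),
      channels = ch,
      source_group = model$group,
      factor_index = f
    )
  }
  class(rois) <- "roi_set"
  dedupe_roi_names(rois)
}

# append a counter to repeated region names so ROI labels stay unique
dedupe_roi_names <- function(rois) {
  nm <- vapply(rois, `[[`, "", "name")
  dup <- stats::ave(seq_along(nm), nm, FUN = seq_along)
  nm <- ifelse(dup > 1, paste0(nm, ".", dup), nm)
  for (i in seq_along(rois)) rois[[i]]$name <- nm[i]
  rois
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set: %d ROIs>\n", length(x)))
  for (r in x) cat(sprintf("  %-28s %3d channels (group %s, factor %d)\n",
                           r$name, length(r$channels),
                           r$source_group %||% "?", r$factor_index))
  invisible(x)
}

#' Group-wise ROI derivation
#'
#' Runs a separate spatial PCA per diagnostic group and pools the resulting
#' ROIs into one set used for all participants in the later model and
#' decoding stages.
#'
#' @param energy channel-level energy table.
#' @param meta cohort metadata.
#' @param montage montage data.frame.
#' @param groups diagnostic groups to analyse.
#' @param cumulative_target,loading_threshold see [spatial_pca()] /
#'   [factors_to_rois()].
#' @return pooled `roi_set`; the per-group factor models are attached as
#'   attribute `"models"`.
#' @export
derive_rois <- function(energy, meta, montage, groups = c("fxs", "control"),
                        cumulative_target = 0.60, loading_threshold = 0.40) {
  models <- list(); pooled <- list()
  for (g in groups) {
    m <- spatial_pca(build_observation_matrix(energy, meta, g),
                     cumulative_target, group = g)
    models[[g]] <- m
    pooled <- c(pooled, unclass(factors_to_rois(m, montage, loading_threshold)))
  }
  class(pooled) <- "roi_set"
  pooled <- dedupe_roi_names(pooled)
  attr(pooled, "models") <- models
  pooled
}

#' Planted-truth ROI set from a simulation config
#'
#' Channel sets straight from the generator's topography supports — the oracle
#' against which PCA-derived ROIs are compared, and a fast stand-in when the
#' ROI-derivation stage itself is not under study.
#'
#' @param config a [sim_config()].
#' @return `roi_set` with one ROI per planted source.
#' @export
planted_rois <- function(config) {
  sup <- attr(config$topographies, "support")
  if (is.null(sup)) {
    sup <- apply(config$topographies != 0, 2, which, simplify = FALSE)
    names(sup) <- colnames(config$topographies) %||%
      paste0("source", seq_along(sup))
  }
  rois <- lapply(seq_along(sup), function(k) list(
    name = names(sup)[k],
    channels = config$montage$channel[sup[[k]]],
    source_group = "planted",
    factor_index = k
  ))
  class(rois) <- "roi_set"
  rois
}
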