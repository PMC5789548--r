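#' Pipeline configuration
#'
#' One flat configuration object covering every stage: simulation, cleaning,
#' energy, ROI derivation, mixed models, decoding and significance. Unknowns
#' default to the documented design choices of their stages; the full config
#' is hashed into the run manifest so a run is reproducible from its artifact
#' bundle alone.
#'
#' @param sim a [sim_config()].
#' @param filter,low,high bandpass stage toggle and band (Hz).
#' @param rereference average-reference stage toggle.
#' @param reject,reject_threshold artifact-rejection toggle and muV threshold.
#' @param energy_mode evoked-subtraction mode, see [subtract_evoked()].
#' @param roi_source `"pca"` (group-wise spatial PCA, the full method) or
#'   `"planted"` (generator-truth channel sets, for calibration work).
#' @param cumulative_target,loading_threshold spatial-PCA settings.
#' @param lmm,lmm_sweep mixed-model stage toggle and covariance sweep toggle.
#' @param decode decoding stage toggle.
#' @param svm_cost,svm_gamma SVM hyperparameters.
#' @param alphas family significance levels.
#' @param calibration_targets printed threshold pair (percent) used to pin the
#'   sidedness/multiplicity convention; `NULL` for plain one-sided Bonferroni.
#' @param write_channel_energy also write the (large) channel-level table.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            filter = TRUE, low = 1, high = 50,
                            rereference = TRUE,
                            reject = TRUE, reject_threshold = 100,
                            energy_mode = "per_presentation_index",
                            roi_source = c("pca", "planted"),
                            cumulative_target = 0.60, loading_threshold = 0.40,
                            lmm = TRUE, lmm_sweep = TRUE,
                            decode = TRUE, svm_cost = 1, svm_gamma = 1,
                            alphas = c(p05 = 0.05, p01 = 0.01),
                            calibration_targets = c(62.96, 64.35),
                            write_channel_energy = FALSE) {
  cfg <- list(sim = sim, filter = filter, low = low, high = high,
              rereference = rereference,
              reject = reject, reject_threshold = reject_threshold,
              energy_mode = energy_mode, roi_source = match.arg(roi_source),
              cumulative_target = cumulative_target,
              loading_threshold = loading_threshold,
              lmm = lmm, lmm_sweep = lmm_sweep, decode = decode,
              svm_cost = svm_cost, svm_gamma = svm_gamma,
              alphas = alphas, calibration_targets = calibration_targets,
              write_channel_energy = write_channel_energy)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

# ROI aggregation of an existing channel-level energy table (unweighted mean
# of member-channel energies per kept epoch).
aggregate_to_rois <- function(channel_table, rois) {
  map <- data.table::rbindlist(lapply(rois, function(r)
    data.table::data.table(region = r$channels, roi = r$name)))
  dt <- data.table::as.data.table(channel_table)
  merged <- merge(dt, map, by = "region", allow.cartesian = TRUE)
  agg <- merged[, list(energy = mean(energy)),
                by = c("participant_id", "subgroup", "stimulus",
                       "presentation", "roi")]
  data.table::setnames(agg, "roi", "region")
  as.data.frame(agg[order(agg$participant_id, agg$stimulus,
                          agg$presentation, agg$region), ])
}

#' Run the full repetition-suppression pipeline
#'
#' simulate -> preprocess -> channel energies -> ROIs -> mixed-model ladder ->
#' single-trial features -> decoding -> significance, streaming participants
#' so the full epoch tensors never need to be held in memory together. Stages
#' can be toggled off via the config; later stages depending on a disabled
#' stage are skipped.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the artifact bundle (CSV/JSON).
#' @return report bundle: meta, rejection log, channel- and ROI-level energy
#'   tables, `roi_set`, ladder result, post hoc table (or refusal note),
#'   feature matrix, decoding result with significance flags, thresholds, and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  meta <- make_cohort_meta(sim)
  chan_tabs <- vector("list", nrow(meta))
  logs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    ep <- generate_participant(sim, meta[i, ])
    pp <- preprocess_participant(ep, low = config$low, high = config$high,
                                 threshold = config$reject_threshold,
                                 filter = config$filter,
                                 rereference = config$rereference,
                                 reject = config$reject)
    chan_tabs[[i]] <- energy_table(list(pp$epochs), meta, rois = NULL,
                                   mode = config$energy_mode)
    logs[[i]] <- pp$log
  }
  channel_table <- as.data.frame(data.table::rbindlist(chan_tabs))
  rejection_log <- if (config$reject)
    as.data.frame(data.table::rbindlist(logs)) else NULL

  rois <- if (config$roi_source == "pca") {
    derive_rois(channel_table, meta, sim$montage,
                cumulative_target = config$cumulative_target,
                loading_threshold = config$loading_threshold)
  } else {
    planted_rois(sim)
  }
  roi_table <- aggregate_to_rois(channel_table, rois)

  ladder <- posthoc <- posthoc_note <- NULL
  if (config$lmm) {
    ladder <- run_ladder(roi_table, meta, sweep = config$lmm_sweep)
    posthoc <- tryCatch(posthoc_pairwise(ladder),
                        error = function(e) {
                          posthoc_note <<- conditionMessage(e); NULL
                        })
  }

  features <- decoding <- thresholds <- convention <- plan <- NULL
  if (config$decode) {
    features <- build_rs_features(roi_table, meta)
    ids <- lapply(split(features$participant, features$label), unique)
    plan <- make_fold_plan(ids[[1]], ids[[2]])
    decoding <- run_decoding(features, plan,
                             cost = config$svm_cost, gamma = config$svm_gamma)
    n_eval <- 2 * length(plan$ids_b) * sim$n_stimuli
    m <- ncol(features$x)
    convention <- if (!is.null(config$calibration_targets))
      calibrate_convention(n = n_eval, m = m,
                           alphas = unname(config$alphas),
                           targets = config$calibration_targets) else NULL
    thresholds <- if (!is.null(convention)) {
      stats::setNames(convention$thresholds, names(config$alphas))
    } else {
      vapply(config$alphas, function(a)
        as.numeric(binomial_threshold(n_eval, a, m = m)), 0)
    }
    decoding <- flag_significant(decoding, thresholds)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rseeg")),
    config_hash = config_hash(config),
    seed = sim$seed,
    n_participants = nrow(meta),
    n_epochs_total = nrow(meta) * sim$n_stimuli * sim$n_presentations,
    n_epochs_rejected = if (is.null(rejection_log)) 0L else nrow(rejection_log),
    n_channel_energy_rows = nrow(channel_table),
    n_roi_energy_rows = nrow(roi_table),
    n_rois = length(rois),
    n_features = if (is.null(features)) NA_integer_ else ncol(features$x),
    n_trials = if (is.null(features)) NA_integer_ else nrow(features$x),
    n_bootstrap_subsets = if (is.null(plan)) NA_integer_ else length(plan$subsets),
    thresholds = thresholds,
    convention = convention[c("sided", "m_eff")],
    covariance_selected = if (is.null(ladder)) NA else ladder$covariance_selected
  )
  bundle <- list(config = config, meta = meta, rejection_log = rejection_log,
                 channel_table = channel_table, rois = rois,
                 roi_table = roi_table, ladder = ladder, posthoc = posthoc,
                 posthoc_note = posthoc_note, features = features, plan = plan,
                 decoding = decoding, thresholds = thresholds,
                 convention = convention, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  w(bundle$meta, "meta.csv")
  w(bundle$rejection_log, "rejection_log.csv")
  w(bundle$roi_table, "energy_rois.csv")
  if (isTRUE(bundle$config$write_channel_energy))
    w(bundle$channel_table, "energy_channels.csv")
  jsonlite::write_json(
    lapply(unclass(bundle$rois), function(r) r[c("name", "channels",
                                                 "source_group", "factor_index")]),
    file.path(out_dir, "rois.json"), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(bundle$ladder)) {
    jsonlite::write_json(list(
      steps = bundle$ladder$steps,
      aic_by_covariance = as.list(bundle$ladder$aic_by_covariance),
      covariance_selected = bundle$ladder$covariance_selected,
      fixed_effect_tests = cbind(term = rownames(bundle$ladder$fixed_effect_tests),
                                 bundle$ladder$fixed_effect_tests)
    ), file.path(out_dir, "lmm_report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
    w(bundle$posthoc, "posthoc.csv")
  }
  if (!is.null(bundle$decoding)) {
    w(as.data.frame(bundle$decoding), "decoding.csv")
    jsonlite::write_json(list(thresholds = as.list(bundle$thresholds),
                              convention = bundle$convention),
                         file.path(out_dir, "significance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
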