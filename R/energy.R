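#' Remove the phase-locked (evoked) waveform
#'
#' Isolates non-phase-locked (induced) activity: for every presentation index
#' p, the mean waveform over the stimuli at that same p (per participant and
#' channel) is subtracted from each epoch. Because every presentation position
#' has one exemplar per pseudoword train, the phase-locked component — which is
#' identical across stimuli — cancels, while activity whose phase varies from
#' epoch to epoch survives. Rejected epochs are excluded from the subtracted
#' mean.
#'
#' Subtracting a k-stimulus mean shrinks the residual's expected energy by
#' the factor (1 - 1/k); because artifact rejection makes k vary across
#' presentation indices, the residuals are rescaled by sqrt(k / (k - 1)) so
#' that expected energy is independent of how many exemplars entered the
#' evoked estimate (otherwise the rejection pattern leaks a spurious
#' participant-level repetition structure into the energies).
#'
#' @param epochs an `epoch_tensor`.
#' @param mode `"per_presentation_index"` (default) or `"none"` (identity).
#' @return the `epoch_tensor` with the evoked estimate removed.
#' @export
subtract_evoked <- function(epochs, mode = c("per_presentation_index", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(epochs)
  d <- dim(epochs$data)
  if (d[1] < 2) stop("evoked subtraction requires at least 2 stimuli")
  w <- array(as.numeric(epochs$mask), dim = d)     # recycles over C, T
  n_kept <- pmax(colSums(epochs$mask), 1L)         # kept stimuli per p
  avg <- colSums(epochs$data * w) / n_kept         # (P, C, T) mean over kept s
  epochs$data <- epochs$data - rep(avg, each = d[1])
  corr <- sqrt(n_kept / pmax(n_kept - 1L, 1L))     # energy-bias correction
  epochs$data <- epochs$data * rep(rep(corr, each = d[1]), times = d[3] * d[4])
  epochs
}

#' Normalize one repetition series
#'
#' The time series of all presentations of one pseudoword (one participant,
#' one channel) are divided by the pooled sample standard deviation
#' (denominator N-1) of the concatenated kept presentations, making the SD of
#' every pseudoword series equal to one. Energies computed afterwards are
#' therefore unitless and comparable across channels and participants.
#'
#' @param series numeric matrix, presentations x samples.
#' @param kept logical vector marking non-rejected presentations.
#' @return list with `series` (normalized; rejected rows dropped), `kept`,
#'   and `record` (the pooled-SD divisor).
#' @export
normalize_repetition_series <- function(series, kept = rep(TRUE, nrow(series))) {
  series <- as.matrix(series)
  x <- series[kept, , drop = FALSE]
  if (length(x) < 2) stop("degenerate series: fewer than 2 pooled samples")
  sd_pooled <- stats::sd(as.vector(x))
  if (!is.finite(sd_pooled) || sd_pooled == 0)
    stop("degenerate series: pooled standard deviation is zero")
  list(series = x / sd_pooled, kept = kept,
       record = c(sd_pooled = sd_pooled))
}

#' Signal energy of one epoch
#'
#' E = sum of squared amplitudes over all samples of the segmented window.
#'
#' @param epoch numeric vector or matrix of (normalized) amplitudes.
#' @return non-negative scalar energy.
#' @export
compute_energy <- function(epoch) {
  stopifnot(all(is.finite(epoch)))
  sum(epoch^2)
}

# Vectorized per-participant energies: evoked subtraction (optional), per
# (channel, stimulus) series normalization over kept presentations, then
# E[s, p, ch] = sum over samples of squared normalized amplitude.
# Returns list(E = S x P x C array with NA at rejected epochs,
#              records = data.frame of normalization divisors).
participant_energy <- function(epochs, mode = "per_presentation_index") {
  epochs <- subtract_evoked(epochs, mode)
  d <- dim(epochs$data)                                # S P C T
  kept_n <- rowSums(epochs$mask)                       # per stimulus
  # mask expanded over (S, P): zero out rejected epochs for the pooled sums
  w <- array(as.numeric(epochs$mask), dim = d)         # recycles over C, T
  xw <- epochs$data * w
  # pooled first and second moments per (stimulus, channel) over kept (p, t)
  m1 <- matrix(aperm(xw, c(2, 4, 1, 3)), nrow = d[2] * d[4])      # (P*T) x (S*C)
  n_pool <- kept_n * d[4]
  mu <- colSums(m1) / rep(n_pool, times = d[3])
  ss <- colSums(m1^2)
  sd_pooled <- sqrt(pmax(ss - rep(n_pool, d[3]) * mu^2, 0) /
                      (rep(n_pool, d[3]) - 1))
  dim(sd_pooled) <- c(d[1], d[3])                      # S x C
  bad <- which(sd_pooled == 0 & kept_n > 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("degenerate series: zero pooled SD at stimulus ", bad[1, 1],
         ", channel ", bad[1, 2])
  # per-epoch energies of the normalized series
  e_raw <- colSums(aperm(epochs$data^2, c(4, 1, 2, 3)))           # S x P x C
  div <- aperm(array(sd_pooled^2, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  E <- e_raw / div
  # logical (S x P) subscript recycles over the channel dimension
  E[!epochs$mask] <- NA_real_
  rec <- data.frame(participant_id = epochs$participant_id,
                    channel = rep(epochs$channel_names, each = d[1]),
                    stimulus = rep(seq_len(d[1]), times = d[3]),
                    sd_pooled = as.vector(sd_pooled))
  list(E = E, records = rec)
}

#' Long-form energy table for a cohort
#'
#' Runs the energy pipeline (evoked subtraction, repetition-series
#' normalization, per-epoch energy) per channel and, when an ROI set is given,
#' aggregates to regions as the unweighted mean of member-channel energies.
#' Rejected epochs are absent from the table.
#'
#' @param epochs_list list of (preprocessed) `epoch_tensor`s, or the list
#'   returned by [generate_cohort()].
#' @param meta cohort metadata (participant_id, subgroup, ...).
#' @param rois optional `roi_set` from [factors_to_rois()] / [derive_rois()];
#'   `NULL` keeps channel-level rows.
#' @param mode evoked-subtraction mode, see [subtract_evoked()].
#' @return data.frame: participant_id, subgroup, stimulus, presentation,
#'   region, energy. Normalization divisors are attached as attribute
#'   `"records"`.
#' @export
energy_table <- function(epochs_list, meta, rois = NULL,
                         mode = "per_presentation_index") {
  if (!is.null(epochs_list$epochs)) epochs_list <- epochs_list$epochs
  rows <- vector("list", length(epochs_list))
  recs <- vector("list", length(epochs_list))
  for (i in seq_along(epochs_list)) {
    ep <- epochs_list[[i]]
    pe <- participant_energy(ep, mode)
    d <- dim(pe$E)
    en <- pe$E
    if (!is.null(rois)) {
      agg <- array(NA_real_, dim = c(d[1], d[2], length(rois)))
      for (r in seq_along(rois)) {
        ch <- match(rois[[r]]$channels, ep$channel_names)
        if (anyNA(ch)) stop("ROI '", rois[[r]]$name, "' references unknown channel")
        agg[, , r] <- apply(en[, , ch, drop = FALSE], c(1, 2), mean)
      }
      en <- agg
      regions <- vapply(rois, `[[`, "", "name")
    } else {
      regions <- ep$channel_names
    }
    keep <- as.vector(ep$mask)
    sub <- meta$subgroup[match(ep$participant_id, meta$participant_id)]
    dt <- data.table::data.table(
      participant_id = ep$participant_id,
      subgroup = sub,
      stimulus = rep(seq_len(d[1]), times = d[2] * length(regions)),
      presentation = rep(rep(seq_len(d[2]), each = d[1]), times = length(regions)),
      region = rep(regions, each = d[1] * d[2]),
      energy = as.vector(en)
    )
    rows[[i]] <- dt[rep(keep, length(regions))]
    recs[[i]] <- pe$records
  }
  out <- as.data.frame(data.table::rbindlist(rows))
  attr(out, "records") <- do.call(rbind, recs)
  out
}
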