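# Extend a segment on both sides by autoregressive forecasting (order <= 20,
# Yule-Walker). A short epoch filtered with a 1-Hz high-pass edge would
# otherwise carry the boundary transient across most of the window; the AR
# extension continues the epoch's own oscillatory content so the filter sees
# no discontinuity at the segment edges. Falls back to odd reflection when
# the AR fit is unavailable.
ar_extend <- function(v, pad) {
  fit <- tryCatch(stats::ar.yw(v, aic = TRUE, order.max = 20, demean = TRUE),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    fwd <- as.numeric(stats::predict(fit, newdata = v, n.ahead = pad,
                                     se.fit = FALSE))
    bwd <- rev(as.numeric(stats::predict(fit, newdata = rev(v), n.ahead = pad,
                                         se.fit = FALSE)))
    return(c(bwd, v, fwd))
  }
  # degenerate series (e.g. constant): value-continuous constant extension
  c(rep(v[1], pad), v, rep(v[length(v)], pad))
}

#' Zero-phase bandpass filter
#'
#' Applies a 4th-order Butterworth bandpass forward and backward (zero-phase,
#' so energy windows are not shifted in latency) to every channel of every
#' epoch. Because the epochs are short relative to the high-pass ringing,
#' each segment is extended by autoregressive forecasting (two epoch lengths
#' per side) before filtering and trimmed afterwards.
#'
#' @param epochs an `epoch_tensor`.
#' @param low,high band edges in Hz (defaults 1-50).
#' @return the filtered `epoch_tensor` (same shape).
#' @export
bandpass_filter <- function(epochs, low = 1, high = 50) {
  fs <- epochs$sample_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < sample_rate/2")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  d <- dim(epochs$data)
  Tn <- d[4]
  pad <- 2L * Tn
  keep <- pad + seq_len(Tn)
  x <- matrix(aperm(epochs$data, c(4, 1, 2, 3)), nrow = Tn)
  for (j in seq_len(ncol(x)))
    x[, j] <- signal::filtfilt(bf, ar_extend(x[, j], pad))[keep]
  epochs$data <- aperm(array(x, dim = d[c(4, 1, 2, 3)]), c(2, 3, 4, 1))
  epochs
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean over channels, so at every
#' (stimulus, presentation, sample) the channel mean is zero. Idempotent.
#'
#' @param epochs an `epoch_tensor` with at least 2 channels.
#' @return the re-referenced `epoch_tensor`.
#' @export
rereference_average <- function(epochs) {
  d <- dim(epochs$data)
  if (d[3] < 2) stop("average reference requires >= 2 channels")
  x <- matrix(aperm(epochs$data, c(3, 1, 2, 4)), nrow = d[3])
  x <- sweep(x, 2, colMeans(x))
  epochs$data <- aperm(array(x, dim = d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  epochs
}

#' Amplitude-threshold artifact rejection
#'
#' Marks an epoch rejected iff any sample on any channel strictly exceeds
#' +/- `threshold` muV (values exactly at the threshold are kept). Rejected
#' epochs are excluded from every downstream statistic via the tensor's mask.
#'
#' @param epochs an `epoch_tensor`.
#' @param threshold rejection threshold in muV (default 100).
#' @return list with `epochs` (mask updated) and `log`, a data.frame of
#'   rejected (stimulus, presentation) indices plus kept/total counts in
#'   attributes `kept_count` / `total_count`.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  if (threshold <= 0) stop("threshold must be positive")
  d <- dim(epochs$data)
  m <- abs(matrix(epochs$data, nrow = d[1] * d[2]))
  peak <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  bad <- matrix(peak > threshold, d[1], d[2])
  epochs$mask <- epochs$mask & !bad
  idx <- which(bad, arr.ind = TRUE)
  log <- data.frame(participant_id = rep(epochs$participant_id, nrow(idx)),
                    stimulus = idx[, 1], presentation = idx[, 2])
  log <- log[order(log$stimulus, log$presentation), , drop = FALSE]
  rownames(log) <- NULL
  attr(log, "kept_count") <- sum(epochs$mask)
  attr(log, "total_count") <- length(epochs$mask)
  list(epochs = epochs, log = log)
}

#' Standard cleaning chain for one participant
#'
#' Bandpass filter, average re-reference, then amplitude rejection — the
#' documented order for this paradigm.
#'
#' @param epochs an `epoch_tensor`.
#' @param low,high filter band (Hz); set `filter = FALSE` to skip filtering
#'   (useful when the input is already band-limited).
#' @param threshold rejection threshold, muV.
#' @param filter,rereference,reject stage toggles.
#' @return list with `epochs` and rejection `log`.
#' @export
preprocess_participant <- function(epochs, low = 1, high = 50, threshold = 100,
                                   filter = TRUE, rereference = TRUE,
                                   reject = TRUE) {
  if (filter) epochs <- bandpass_filter(epochs, low, high)
  if (rereference) epochs <- rereference_average(epochs)
  log <- NULL
  if (reject) {
    r <- reject_artifacts(epochs, threshold)
    epochs <- r$epochs; log <- r$log
  }
  list(epochs = epochs, log = log)
}
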