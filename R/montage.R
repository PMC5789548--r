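#' Synthetic high-density EEG montage
#'
#' Builds a deterministic sensor layout for a dense-array net with the face and
#' neck ring already excluded (the analysis operates on the retained scalp
#' channels only). Channels are placed on a sunflower (Fibonacci) disc so that
#' coverage is approximately uniform; `x` is the left-right axis (positive =
#' right), `y` the posterior-anterior axis (positive = anterior), both in
#' head-radius units.
#'
#' @param n_channels number of scalp channels (default 99).
#' @return data.frame with columns `channel`, `x`, `y`, `region`.
#' @export
default_montage <- function(n_channels = 99) {
  stopifnot(n_channels >= 1)
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt(i / n_channels) * 0.95
  theta <- i * golden
  x <- r * sin(theta)
  y <- r * cos(theta)
  data.frame(
    channel = paste0("E", i),
    x = x, y = y,
    region = mapply(scalp_region, x, y),
    stringsAsFactors = FALSE
  )
}

# Anterior-posterior band x laterality labelling used for ROI naming.
scalp_region <- function(x, y) {
  band <- if (abs(x) >= 0.60 && abs(y) < 0.45) {
    "temporal"
  } else if (y > 0.30) {
    "frontal"
  } else if (y >= -0.30) {
    "central"
  } else {
    "occipital"
  }
  side <- if (x >= 0.20) "right" else if (x <= -0.20) "left" else "midline"
  if (band == "temporal" && side == "midline") side <- if (x >= 0) "right" else "left"
  paste(band, side, sep = "-")
}

#' Name a channel set from its spatial centroid
#'
#' @param channels character vector of channel labels.
#' @param montage montage data.frame from [default_montage()].
#' @return a region label such as "frontal-right".
#' @export
roi_name_from_centroid <- function(channels, montage) {
  idx <- match(channels, montage$channel)
  if (anyNA(idx)) stop("unknown channel label(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  scalp_region(mean(montage$x[idx]), mean(montage$y[idx]))
}
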