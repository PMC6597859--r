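#' Minimal EEG preprocessing
#'
#' Mirrors the standard continuous-EEG pipeline ahead of TRF fitting:
#' zero-phase anti-aliased decimation to the target rate, a zero-phase
#' 1st-order Butterworth high-pass (default 1 Hz), variance-based bad-channel
#' detection (a channel is bad when its variance is under half or over twice
#' the mean variance of its surrounding channels) with neighbour-mean
#' interpolation, optional re-referencing to the mastoid average, and
#' per-channel z-scoring.
#'
#' Neighbour-mean interpolation is a geometry-free stand-in for spline
#' interpolation: it needs no electrode coordinates, which synthetic montages
#' do not have. The neighbourhood size is a configuration knob because the
#' notion of "surrounding" channels is montage-specific.
#'
#' @param raw Numeric time x channels matrix.
#' @param fs_in Input sampling rate in Hz.
#' @param fs_out Target rate (default 128); pass `fs_in` to skip resampling.
#' @param highpass_hz High-pass cutoff in Hz (default 1; 0 disables).
#' @param neighbor_k Channels on each side counted as neighbours (default 2).
#' @param var_lo,var_hi Bad-channel variance bounds relative to the
#'   neighbour mean (defaults 0.5 and 2).
#' @param mastoids Indices or labels of the mastoid channels, or `NULL` to
#'   skip re-referencing (a warning is issued if requested labels are
#'   absent).
#' @param channel_labels Optional channel labels.
#' @return An [eeg_trial()] at `fs_out`, z-scored per channel, with
#'   attribute `bad_channels` listing interpolated channel indices.
#' @export
preprocess_eeg <- function(raw, fs_in, fs_out = 128, highpass_hz = 1,
                           neighbor_k = 2, var_lo = 0.5, var_hi = 2,
                           mastoids = NULL, channel_labels = colnames(raw)) {
  raw <- as.matrix(raw)
  nch <- ncol(raw)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  x <- if (fs_out < fs_in)
    vapply(seq_len(nch), function(j) decimate_series(raw[, j], fs_in, fs_out),
           numeric(ceiling(nrow(raw) * fs_out / fs_in)))
  else raw
  if (highpass_hz > 0) {
    hp <- signal::butter(1, highpass_hz / (fs_out / 2), type = "high")
    ## pad by ~3 time constants of the cutoff to absorb filter transients
    pad <- round(3 * fs_out / highpass_hz)
    x <- apply(x, 2, function(col) padded_filtfilt(hp, col, pad))
  }
  ## bad channels: variance vs mean variance of the surrounding channels
  v <- apply(x, 2, stats::var)
  bad <- integer(0)
  for (j in seq_len(nch)) {
    nb <- setdiff(max(1, j - neighbor_k):min(nch, j + neighbor_k), j)
    ref <- mean(v[nb])
    if (ref > 0 && (v[j] < var_lo * ref || v[j] > var_hi * ref)) bad <- c(bad, j)
  }
  for (j in bad) {
    nb <- setdiff(max(1, j - neighbor_k):min(nch, j + neighbor_k), union(j, bad))
    if (length(nb)) x[, j] <- rowMeans(x[, nb, drop = FALSE])
  }
  if (!is.null(mastoids)) {
    if (is.character(mastoids)) mastoids <- match(mastoids, channel_labels)
    if (anyNA(mastoids)) {
      warning("mastoid channels not found; skipping re-reference")
    } else {
      ref <- rowMeans(x[, mastoids, drop = FALSE])
      x <- x - ref
      keep <- setdiff(seq_len(nch), mastoids)
      x <- x[, keep, drop = FALSE]
      channel_labels <- channel_labels[keep]
      bad <- match(bad[bad %in% keep], keep)
    }
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(x, 2, mu, `-`), 2, sdv, `/`)
  out <- eeg_trial(x, fs_out, channel_labels)
  attr(out, "bad_channels") <- bad
  out
}
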