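#' Acoustic envelope time series
#'
#' Container for a one-dimensional nonnegative amplitude time series with its
#' sampling rate. Envelopes are what every stimulus representation in this
#' package is derived from: the amplitude-binned envelope, the SPL (dB)
#' envelope, and the onset/offset/derivative envelopes.
#'
#' @param values Numeric vector of amplitude samples. Must be finite and, for
#'   a raw envelope, nonnegative (the SPL transform relaxes this for its
#'   output; see [spl_envelope()]).
#' @param fs Sampling rate in Hz (samples/second), positive.
#' @param nonnegative Logical; enforce the `values >= 0` invariant. The SPL
#'   transform sets this to `FALSE` for its (dB-scaled, possibly negative)
#'   output.
#' @return An object of class `"envelope"`: a numeric vector with attributes
#'   `fs` and `unit`.
#' @examples
#' env <- envelope(abs(sin(seq(0, 10, length.out = 1280))), fs = 128)
#' @export
envelope <- function(values, fs, nonnegative = TRUE) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("an envelope needs at least 2 samples")
  if (!all(is.finite(values))) stop("envelope values must be finite")
  if (nonnegative && any(values < 0)) stop("envelope values must be nonnegative")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  structure(values, fs = as.numeric(fs), class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d samples @ %g Hz (%.2f s), range [%.4g, %.4g]\n",
              length(x), attr(x, "fs"), length(x) / attr(x, "fs"),
              min(x), max(x)))
  invisible(x)
}

#' Sampling rate accessor
#' @param x An object with an `fs` attribute (envelope, stimulus
#'   representation, EEG trial, TRF model).
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(x) attr(x, "fs")

## Analytic signal by the FFT half-spectrum method: zero the negative
## frequencies, double the positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

## One integer-factor decimation stage: zero-phase order-8 Chebyshev type I
## low-pass (0.05 dB ripple, cutoff 0.8 of the target Nyquist), then take
## every r-th sample. This is the classic MATLAB-style IIR decimator.
## The even-order Chebyshev passband ripple puts DC gain at -Rp dB, which
## filtfilt squares and staging compounds; renormalising b to unit DC gain
## keeps envelope amplitudes calibrated.
antialias_cheby <- function(ratio) {
  flt <- signal::cheby1(8, 0.05, 0.8 / ratio)
  flt$b <- flt$b * (sum(flt$a) / sum(flt$b))
  flt
}

## Zero-phase filtering with odd-reflection end padding to suppress the edge
## transients of plain forward-backward filtering.
padded_filtfilt <- function(flt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 3L * (length(flt$a) + length(flt$b)))
  pad <- min(pad, n - 1L)
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

decimate_stage <- function(x, r) {
  if (r == 1L) return(x)
  y <- padded_filtfilt(antialias_cheby(r), x)
  y[seq.int(1L, length(y), by = r)]
}

#' Resample a series to a lower rate with anti-alias filtering
#'
#' Zero-phase IIR anti-aliased decimation. Integer rate ratios are handled by
#' staged Chebyshev type I decimation (each stage by a factor of at most 12);
#' a non-integer residual factor is handled by one final low-pass plus cubic
#' spline resampling onto the exact output grid, so e.g. 44100 Hz audio maps
#' cleanly to 128 Hz. Output length is `ceiling(length(x) * fs_out / fs_in)`.
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Input and output sampling rates in Hz; `fs_out` must be
#'   smaller than `fs_in`.
#' @return Numeric vector at rate `fs_out`.
#' @export
decimate_series <- function(x, fs_in, fs_out) {
  if (fs_out >= fs_in) stop("fs_out must be smaller than fs_in")
  n_out <- ceiling(length(x) * fs_out / fs_in)
  fs_cur <- fs_in
  while (fs_cur / fs_out >= 24 || (fs_cur / fs_out > 12 && fs_cur %% fs_out != 0)) {
    ## peel off integer stages while the remaining factor is large
    r <- min(10L, floor(fs_cur / fs_out / 2))
    x <- decimate_stage(x, r)
    fs_cur <- fs_cur / r
  }
  ratio <- fs_cur / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    x <- decimate_stage(x, as.integer(round(ratio)))
    length(x) <- n_out  # staged ceilings compose to ceiling of the product
    x[is.na(x)] <- x[max(which(!is.na(x)))]
    x
  } else {
    x <- padded_filtfilt(antialias_cheby(ratio), x)
    t_in <- (seq_along(x) - 1) / fs_cur
    t_out <- (seq_len(n_out) - 1) / fs_out
    sf <- stats::splinefun(t_in, x, method = "natural")
    out <- sf(pmin(t_out, max(t_in)))
    out
  }
}

#' Extract the amplitude envelope of an audio signal
#'
#' Computes the modulus of the analytic (Hilbert) signal of the audio and
#' decimates it to the target rate with zero-phase anti-alias filtering.
#' This is the canonical broadband envelope used as the input feature for
#' TRF estimation.
#'
#' @param audio Numeric vector of audio samples (mono). Must be finite and at
#'   least 16 samples long.
#' @param fs_in Audio sampling rate in Hz.
#' @param fs_out Target envelope rate in Hz (default 128); must be below
#'   `fs_in`.
#' @return An [envelope()] at `fs_out`. Values are nonnegative; length is
#'   `ceiling(length(audio) * fs_out / fs_in)`.
#' @examples
#' x <- cos(2 * pi * 440 * seq(0, 1, by = 1 / 8192))
#' env <- extract_envelope(x, 8192, 128)
#' @export
extract_envelope <- function(audio, fs_in, fs_out = 128) {
  audio <- as.numeric(audio)
  if (!all(is.finite(audio))) stop("audio must be finite")
  if (length(audio) < 16L) stop("audio too short for analytic-signal extraction")
  if (fs_out >= fs_in) stop("fs_out must be smaller than fs_in")
  env <- Mod(analytic_signal(audio))
  env <- decimate_series(env, fs_in, fs_out)
  ## zero-phase IIR filtering can produce tiny negative excursions near edges
  env[env < 0] <- 0
  envelope(env, fs_out)
}
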