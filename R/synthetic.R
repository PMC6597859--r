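#' Configuration for the synthetic stimulus/EEG generator
#'
#' Defines the study conditions the generator emulates: an amplitude-
#' modulated envelope with a broad (log-uniform) amplitude distribution and a
#' right-skewed modulation-rate spectrum, and EEG formed as a sum over
#' amplitude bins of bin-specific response kernels convolved with the binned
#' envelope, plus 1/f background noise. Kernel magnitude grows and latency
#' shrinks with amplitude bin, the structure the amplitude-binned TRF is
#' designed to recover.
#'
#' @param n_trials Number of trials (default 20).
#' @param trial_seconds Trial duration in seconds (default 60).
#' @param fs Sampling rate in Hz (default 128; envelope-level simulation).
#' @param n_channels EEG channels (default 32).
#' @param n_bins Number of amplitude bins B (default 8) of `width_db` each.
#' @param width_db Bin width in dB (default 8).
#' @param latency_shift Kernel latency increase in ms per bin step away from
#'   the loudest bin (default 11).
#' @param gain_profile Per-bin kernel gains, ascending amplitude; default a
#'   linear ramp from 0.35 to 1 so magnitude grows with amplitude.
#' @param kernel_shape List defining the biphasic response prototype: fields
#'   `p1_ms`, `n1_ms` (lobe centres), `p1_width_ms`, `n1_width_ms` (Gaussian
#'   SDs) and `p1_gain`, `n1_gain` (lobe magnitudes). Defaults put P1 at
#'   45 ms and N1 at 110 ms so that even the most-shifted bin's peaks stay
#'   inside the standard search windows.
#' @param snr_db Broadband signal-to-noise power ratio in dB (default 0);
#'   `Inf` disables noise.
#' @param noise_exponent Slope of the 1/f^a noise spectrum (default 1).
#' @param amplitude_range_db Span of the log-uniform amplitude law (default
#'   64 dB = 8 bins x 8 dB).
#' @param segment_mean_s,segment_range_s Mean and truncation range (seconds)
#'   of the exponential law for modulation segment durations; the default
#'   (0.3 s, truncated to 0.1-2 s) yields the right-skewed, low-frequency-
#'   dominated modulation spectrum of amplitude-modulated noise stimuli.
#' @param transition_s Duration (s) of the raised-cosine transition between
#'   successive amplitude levels (default 0.08).
#' @param stimulus_mode `"repeated"` (one envelope reused across trials, the
#'   AM-noise design; default) or `"distinct"` (fresh envelope per trial).
#' @param envelope_kind `"am"` (log-uniform amplitudes) or `"speech"`
#'   (left-skewed amplitude law in dB, emulating speech envelopes).
#' @param onset_pathway Logical; add an extra response pathway driven by the
#'   onset envelope (default `FALSE`). Used to test combined-model claims.
#' @param onset_gain Gain of the onset pathway kernel.
#' @param topography Optional per-channel weight vector; default a smooth
#'   unimodal (fronto-central-like) bump.
#' @param seed Integer seed; all randomness funnels through it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_trials = 20, trial_seconds = 60, fs = 128,
                       n_channels = 32, n_bins = 8, width_db = 8,
                       latency_shift = 11, gain_profile = NULL,
                       kernel_shape = list(p1_ms = 45, n1_ms = 110,
                                           p1_width_ms = 15, n1_width_ms = 22,
                                           p1_gain = 1, n1_gain = 1.5),
                       snr_db = 0, noise_exponent = 1,
                       amplitude_range_db = 64,
                       segment_mean_s = 0.3, segment_range_s = c(0.1, 2),
                       transition_s = 0.08,
                       stimulus_mode = c("repeated", "distinct"),
                       envelope_kind = c("am", "speech"),
                       onset_pathway = FALSE, onset_gain = 0.5,
                       topography = NULL, seed = 1) {
  stimulus_mode <- match.arg(stimulus_mode)
  envelope_kind <- match.arg(envelope_kind)
  if (trial_seconds < 4) stop("trials must be at least 4 s long")
  if (latency_shift < 0) stop("latency_shift must be nonnegative")
  if (is.null(gain_profile))
    gain_profile <- seq(0.35, 1, length.out = n_bins)
  if (any(gain_profile < 0)) stop("gains must be nonnegative")
  if (length(gain_profile) != n_bins) stop("one gain per bin required")
  if (is.null(topography)) {
    ch <- seq_len(n_channels)
    topography <- exp(-((ch - 0.35 * n_channels)^2) / (2 * (n_channels / 5)^2))
  }
  if (length(topography) != n_channels) stop("one topography weight per channel")
  structure(as.list(environment()), class = "sim_config")
}

## Shared skeleton: draw discrete segment amplitudes (in dB) with truncated-
## exponential durations, hold each level over its segment, smooth the dB
## track with a short Hann kernel (a raised-cosine transition between
## levels), exponentiate and rescale to [0, 1]. Holding the levels keeps the
## amplitude marginal at the drawn law; only the brief transitions mix it.
gen_envelope_db <- function(config, draw_db) {
  n <- round(config$trial_seconds * config$fs)
  lo <- config$segment_range_s[1]; hi <- config$segment_range_s[2]
  ## truncated exponential durations via inverse CDF
  qtrunc <- function(u) {
    r <- 1 / config$segment_mean_s
    Flo <- 1 - exp(-r * lo); Fhi <- 1 - exp(-r * hi)
    -log(1 - (Flo + u * (Fhi - Flo))) / r
  }
  t_end <- config$trial_seconds
  bounds <- numeric(0)
  t_cur <- 0
  while (t_cur < t_end) {
    t_cur <- t_cur + qtrunc(stats::runif(1))
    bounds <- c(bounds, t_cur)
  }
  db <- draw_db(length(bounds))
  grid <- (seq_len(n) - 1) / config$fs
  step <- db[findInterval(grid, c(0, utils::head(bounds, -1)))]
  k <- max(3L, round(config$transition_s * config$fs))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
  w <- w / sum(w)
  padded <- c(rep(step[1], k), step, rep(step[n], k))
  sm <- stats::filter(padded, w, sides = 2)
  sm <- as.numeric(sm)[(k + 1):(k + n)]
  v <- 10^(sm / 20)
  envelope(v / max(v), config$fs)
}

#' Generate an amplitude-modulated noise envelope
#'
#' Draws segment amplitudes log-uniformly over `amplitude_range_db` at
#' segment rates following a truncated exponential duration law, smoothly
#' interpolates the dB track between anchors (monotone cubic, so no
#' overshoot) and rescales to `[0, 1]`. The result has an approximately flat
#' amplitude histogram in dB and a right-skewed modulation spectrum
#' dominated by rates below a few Hz.
#'
#' @param config A [sim_config()].
#' @return An [envelope()] with maximum 1.
#' @export
gen_am_envelope <- function(config) {
  gen_envelope_db(config, function(k)
    stats::runif(k, -config$amplitude_range_db, 0))
}

#' Generate a speech-like envelope
#'
#' As [gen_am_envelope()] but with a left-skewed amplitude law in dB
#' (`-range * Beta(2, 5)`), concentrating samples in the higher amplitude
#' bins the way natural speech envelopes do.
#'
#' @param config A [sim_config()].
#' @return An [envelope()] with maximum 1.
#' @export
gen_speech_envelope <- function(config) {
  gen_envelope_db(config, function(k)
    -config$amplitude_range_db * stats::rbeta(k, 2, 5))
}

#' Bin-specific response kernel bank
#'
#' One biphasic kernel per amplitude bin: a positive P1 lobe followed by a
#' larger negative N1 lobe (Gaussian lobes), scaled by the bin's gain and
#' shifted later in time by `latency_shift` ms per bin step below the loudest
#' bin (bin B, highest amplitude, has zero shift). This encodes the canonical
#' amplitude-intensity dependence: louder means bigger and earlier.
#'
#' @param config A [sim_config()].
#' @param max_lag_ms Upper limit of allowed kernel support (default 400 ms,
#'   matching the default fitting window); a shifted kernel exceeding it is
#'   an error.
#' @return Matrix lags x bins (lag axis starts at 0), with attributes
#'   `lags` (samples) and `fs`.
#' @export
gen_kernel_bank <- function(config, max_lag_ms = 400) {
  ks <- config$kernel_shape
  B <- config$n_bins
  max_shift <- config$latency_shift * (B - 1)
  support_ms <- ks$n1_ms + max_shift + 3 * ks$n1_width_ms
  if (support_ms > max_lag_ms)
    stop("shifted kernels exceed the lag-window support")
  lags <- 0:ceiling(support_ms * config$fs / 1000)
  t_ms <- lags / config$fs * 1000
  proto <- function(t) ks$p1_gain * exp(-(t - ks$p1_ms)^2 / (2 * ks$p1_width_ms^2)) -
                       ks$n1_gain * exp(-(t - ks$n1_ms)^2 / (2 * ks$n1_width_ms^2))
  bank <- vapply(seq_len(B), function(b)
    config$gain_profile[b] * proto(t_ms - config$latency_shift * (B - b)),
    numeric(length(lags)))
  colnames(bank) <- paste0("bin", seq_len(B))
  structure(bank, lags = lags, fs = config$fs)
}

## Gaussian 1/f^a noise: spectrally shape white Gaussian noise (symmetric
## two-sided filter keeps the series real), drop DC, standardise.
pink_noise <- function(n, exponent = 1) {
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)          # two-sided frequency index
  f[1] <- 1                    # placeholder; DC removed below
  shaped <- X * f^(-exponent / 2)
  shaped[1] <- 0
  x <- Re(stats::fft(shaped, inverse = TRUE) / n)
  as.numeric(scale(x))
}

## Zero-padded convolution matching the lagged-design convention:
## out[t] = sum_l k[l+1] * x[t - l], x = 0 outside the trial.
conv_causal <- function(x, kernel, lags) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(lags)) {
    l <- lags[j]
    if (l == 0) out <- out + kernel[j] * x
    else if (l > 0 && l < n) out[(l + 1):n] <- out[(l + 1):n] + kernel[j] * x[1:(n - l)]
  }
  out
}

#' Simulate a dataset of envelopes and EEG with known structure
#'
#' Builds the stimulus envelope(s), bins them with the configured scheme,
#' convolves each bin with its kernel (plus, optionally, an onset-envelope
#' pathway), projects the summed source onto the channels through a smooth
#' unimodal topography, adds 1/f Gaussian noise scaled to the requested
#' broadband SNR, and z-scores each channel per trial (mirroring standard
#' EEG preprocessing). Identical seeds produce bit-identical datasets.
#'
#' @param config A [sim_config()].
#' @return A [trf_dataset()] with an extra `ground_truth` element recording
#'   the kernels, binning, topography, z-scoring scales and the full config.
#' @export
simulate_eeg <- function(config) {
  set.seed(config$seed)
  if (is.finite(config$snr_db) && config$snr_db <= -40)
    warning("SNR at or below -40 dB is indistinguishable from the null")
  M <- config$n_trials
  gen <- if (config$envelope_kind == "am") gen_am_envelope else gen_speech_envelope
  envs <- if (config$stimulus_mode == "repeated") {
    e <- gen(config)
    replicate(M, e, simplify = FALSE)
  } else {
    lapply(seq_len(M), function(i) gen(config))
  }
  bank <- gen_kernel_bank(config)
  lags <- attr(bank, "lags")
  binning <- db_binning(config$width_db, config$n_bins)
  onset_kernel <- if (config$onset_pathway) {
    ks <- config$kernel_shape
    t_ms <- lags / config$fs * 1000
    config$onset_gain * (ks$p1_gain * exp(-(t_ms - ks$p1_ms)^2 / (2 * ks$p1_width_ms^2)) -
                         ks$n1_gain * exp(-(t_ms - ks$n1_ms)^2 / (2 * ks$n1_width_ms^2)))
  } else NULL

  topo <- config$topography
  zscale <- matrix(NA_real_, M, config$n_channels)
  trials <- vector("list", M)
  clean_src <- NULL
  for (j in seq_len(M)) {
    if (is.null(clean_src) || config$stimulus_mode != "repeated") {
      xb <- ab_envelope(envs[[j]], binning, scale = 1)
      src <- numeric(length(envs[[j]]))
      for (b in seq_len(config$n_bins))
        src <- src + conv_causal(xb[, b], bank[, b], lags)
      if (!is.null(onset_kernel))
        src <- src + conv_causal(as.numeric(onset_envelope(envs[[j]])),
                                 onset_kernel, lags)
      clean_src <- src
    }
    clean <- outer(clean_src, topo)
    if (is.finite(config$snr_db)) {
      noise <- vapply(seq_len(config$n_channels), function(ch)
        pink_noise(length(clean_src), config$noise_exponent),
        numeric(length(clean_src)))
      p_clean <- mean(clean^2)
      p_noise <- mean(noise^2)
      noise <- noise * sqrt(p_clean / (p_noise * 10^(config$snr_db / 10)))
      y <- clean + noise
    } else {
      y <- clean
    }
    mu <- colMeans(y)
    sdv <- apply(y, 2, stats::sd)
    sdv[sdv == 0] <- 1  # an all-zero channel stays all-zero
    y <- sweep(sweep(y, 2, mu, `-`), 2, sdv, `/`)
    zscale[j, ] <- sdv
    trials[[j]] <- list(envelope = envs[[j]],
                        eeg = eeg_trial(y, config$fs,
                                        paste0("ch", seq_len(config$n_channels))))
  }
  out <- trf_dataset(trials, config$fs, config$stimulus_mode)
  out$ground_truth <- list(kernels = bank, kernel_lags = lags,
                           binning = binning, topography = topo,
                           onset_kernel = onset_kernel,
                           zscale = zscale, config = config)
  out
}
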