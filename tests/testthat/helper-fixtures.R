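# Shared fixtures: everything is generated in code at test time.

# Small coupled dataset for CV / permutation tests.
tiny_dataset <- function(n_trials = 4, seconds = 8, channels = 4,
                         snr_db = 0, seed = 11, mode = "repeated",
                         bins = 8, snr_inf = FALSE, ...) {
  cfg <- sim_config(n_trials = n_trials, trial_seconds = seconds,
                    n_channels = channels, n_bins = bins,
                    snr_db = if (snr_inf) Inf else snr_db,
                    stimulus_mode = mode, seed = seed, ...)
  simulate_eeg(cfg)
}

# Independent dense ridge oracle: explicit normal equations via solve(),
# reproducing the unpenalised-intercept and diagonal-power-scaled penalty
# conventions from their definition rather than via the package's solver.
ridge_oracle <- function(X, Y, lambda) {
  p <- ncol(X)
  D <- diag(p)
  D[p, p] <- 0
  s <- mean(diag(crossprod(X))[-p])
  solve(crossprod(X) + lambda * s * D, crossprod(X, Y))
}

# Independent FFT analytic-signal oracle (textbook construction, written
# out with explicit index arithmetic).
analytic_oracle <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- rep(0, n)
  w[1] <- 1
  pos <- seq(2, floor((n + 1) / 2))
  w[pos] <- 2
  if (n %% 2 == 0) w[n / 2 + 1] <- 1
  stats::fft(X * w, inverse = TRUE) / n
}

# Nested CV computed the slow, literal way: explicit model fits, averaging,
# prediction and correlation. Used to validate the Gram-statistics fast path.
nested_cv_literal <- function(data, recipe, window, lambda_grid) {
  M <- length(data$trials)
  reps <- lapply(data$trials, function(tr) recipe(tr$envelope))
  fits <- lapply(seq_len(M), function(i)
    lapply(lambda_grid, function(l)
      trf_fit(reps[[i]], data$trials[[i]]$eeg, window, l)))
  C <- ncol(data$trials[[1]]$eeg)
  inner <- array(NA_real_, c(M, M, length(lambda_grid), C))
  test_acc <- matrix(NA_real_, M, C)
  lambda_sel <- numeric(M)
  for (t in seq_len(M)) {
    for (li in seq_along(lambda_grid)) {
      for (v in setdiff(seq_len(M), t)) {
        avg <- trf_average(lapply(setdiff(seq_len(M), c(t, v)),
                                  function(i) fits[[i]][[li]]))
        inner[t, v, li, ] <- pearson_accuracy(predict(avg, reps[[v]]),
                                              data$trials[[v]]$eeg)
      }
    }
    score <- sapply(seq_along(lambda_grid), function(li)
      mean(inner[t, -t, li, ], na.rm = TRUE))
    li_star <- which.max(score)
    lambda_sel[t] <- lambda_grid[li_star]
    avg <- trf_average(lapply(setdiff(seq_len(M), t),
                              function(i) fits[[i]][[li_star]]))
    test_acc[t, ] <- pearson_accuracy(predict(avg, reps[[t]]),
                                      data$trials[[t]]$eeg)
  }
  list(inner = inner, test_accuracies = test_acc, lambda_selected = lambda_sel,
       overall = mean(test_acc))
}

# Minimal 16-bit PCM WAV writer (test-only, independent of the reader).
write_wav16 <- function(samples, fs, path, channels = 1) {
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * channels * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(channels * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
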