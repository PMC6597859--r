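#' Lag window for TRF estimation
#'
#' The range of time lags over which the TRF is estimated, discretised to the
#' sampling grid. Negative lags precede the stimulus sample and provide the
#' pre-stimulus baseline.
#'
#' @param tmin,tmax Window limits in ms, `tmin < tmax`. `tmin` must be at or
#'   below -20 ms if pre-stimulus baseline correction is to be applied later.
#'   Defaults -100 to 400 ms: wide enough to contain the baseline interval
#'   (-20 to 0 ms), the P1 search window (0-130 ms) and the N1 search window
#'   (70-210 ms) with margin.
#' @param fs Sampling rate in Hz.
#' @return Object of class `"lag_window"`: list with `tmin`, `tmax`, `fs`,
#'   integer `lags` (in samples) and `times_ms` (lag times in ms).
#' @export
lag_window <- function(tmin = -100, tmax = 400, fs = 128) {
  if (tmin >= tmax) stop("tmin must be below tmax")
  lmin <- as.integer(round(tmin * fs / 1000))
  lmax <- as.integer(round(tmax * fs / 1000))
  lags <- lmin:lmax
  structure(list(tmin = tmin, tmax = tmax, fs = fs, lags = lags,
                 times_ms = lags / fs * 1000),
            class = "lag_window")
}

#' @export
print.lag_window <- function(x, ...) {
  cat(sprintf("<lag_window> %g..%g ms @ %g Hz (%d lags)\n",
              x$tmin, x$tmax, x$fs, length(x$lags)))
  invisible(x)
}

#' Single EEG trial
#'
#' Time-by-channels matrix of (typically z-scored) EEG with its sampling
#' rate.
#'
#' @param data Numeric time x channels matrix; finite.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one per column.
#' @return Object of class `"eeg_trial"`.
#' @export
eeg_trial <- function(data, fs, channel_labels = colnames(data)) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("EEG data must be finite")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncol(data)))
  colnames(data) <- channel_labels
  structure(data, fs = as.numeric(fs), class = "eeg_trial")
}

#' Lagged (convolutional) design matrix
#'
#' Unrolls the convolution `y(t) = w(tau) * x(t)` into an ordinary linear
#' regression: column `(f, l)` at row `t` holds `rep[t - lag_l, f]`,
#' zero-padded outside the trial (silence outside the recording). Columns are
#' ordered feature-major (all lags of feature 1, then all lags of feature 2,
#' ...), matching the layout of the weight tensor, and an all-ones intercept
#' column is appended last.
#'
#' @param rep A [stim_rep()].
#' @param window A [lag_window()] at the same sampling rate.
#' @return Numeric matrix, `nrow(rep)` x `(lags * features + 1)`.
#' @export
lagged_design <- function(rep, window) {
  if (!isTRUE(all.equal(sample_rate(rep), window$fs)))
    stop("representation and lag window sampling rates differ")
  n <- nrow(rep)
  lags <- window$lags
  L <- length(lags)
  if (L >= n) stop("lag span must be shorter than the trial")
  nf <- ncol(rep)
  X <- matrix(0, n, L * nf + 1L)
  m <- unclass(rep)
  for (f in seq_len(nf)) {
    for (j in seq_len(L)) {
      l <- lags[j]
      col <- (f - 1L) * L + j
      if (l >= 0) {
        if (l < n) X[(l + 1L):n, col] <- m[1:(n - l), f]
      } else {
        X[1:(n + l), col] <- m[(1L - l):n, f]
      }
    }
  }
  X[, L * nf + 1L] <- 1
  X
}

## Ridge normal-equation solve from Gram statistics. The penalty excludes the
## intercept (last row/col) and is scaled by the mean diagonal power of the
## penalised design block, so one lambda grid transfers across
## representations with very different scales.
ridge_solve <- function(G, H, lambda, scale = NULL) {
  p <- nrow(G)
  if (is.null(scale)) scale <- mean(diag(G)[-p])
  A <- G
  if (lambda > 0) {
    idx <- seq_len(p - 1L)
    A[cbind(idx, idx)] <- A[cbind(idx, idx)] + lambda * scale
  }
  R <- tryCatch(chol(A), error = function(e)
    stop("normal equations are rank deficient (singular system at this lambda); ",
         "increase lambda or provide more data", call. = FALSE))
  backsolve(R, backsolve(R, H, transpose = TRUE))
}

make_trf <- function(wmat, window, lambda, feature_labels, channel_labels) {
  L <- length(window$lags)
  nf <- length(feature_labels)
  weights <- array(wmat[seq_len(L * nf), , drop = FALSE],
                   dim = c(L, nf, ncol(wmat)),
                   dimnames = list(NULL, feature_labels, channel_labels))
  structure(list(weights = weights,
                 intercept = wmat[L * nf + 1L, ],
                 window = window, lambda = lambda, fs = window$fs,
                 feature_labels = feature_labels,
                 channel_labels = channel_labels),
            class = "trf_model")
}

#' Fit a single-trial TRF by ridge regression
#'
#' Minimises `||y - X w||^2 + lambda * s * ||w||^2` over the lagged design
#' `X` of the representation, per EEG channel, with an unpenalised intercept.
#' The penalty is scaled by `s`, the mean diagonal of the penalised block of
#' `X'X`, so the same lambda grid is usable across representations.
#'
#' @param rep A [stim_rep()].
#' @param eeg An [eeg_trial()] with the same length and sampling rate.
#' @param window A [lag_window()].
#' @param lambda Nonnegative ridge parameter.
#' @return Object of class `"trf_model"`: list with `weights`
#'   (lags x features x channels array), `intercept`, `window`, `lambda`,
#'   `fs`, `feature_labels`, `channel_labels`.
#' @export
trf_fit <- function(rep, eeg, window, lambda = 0) {
  if (nrow(rep) != nrow(eeg)) stop("representation and EEG lengths differ")
  if (!isTRUE(all.equal(sample_rate(rep), sample_rate(eeg))))
    stop("representation and EEG sampling rates differ")
  if (lambda < 0) stop("lambda must be nonnegative")
  X <- lagged_design(rep, window)
  wmat <- ridge_solve(crossprod(X), crossprod(X, unclass(eeg)), lambda)
  make_trf(wmat, window, lambda, colnames(rep), colnames(eeg))
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<trf_model> %d lags (%g..%g ms) x %d features x %d channels, lambda = %g\n",
              d[1], x$window$tmin, x$window$tmax, d[2], d[3], x$lambda))
  invisible(x)
}

#' Average TRF models element-wise
#'
#' The per-trial models of a training set are combined into one model by
#' averaging their weight tensors (and intercepts).
#'
#' @param models List of `trf_model` objects with identical shape, lag window
#'   and lambda.
#' @return A `trf_model`.
#' @export
trf_average <- function(models) {
  if (!length(models)) stop("no models to average")
  ref <- models[[1]]
  for (m in models) {
    if (!identical(dim(m$weights), dim(ref$weights)) ||
        !identical(m$window$lags, ref$window$lags) ||
        !isTRUE(all.equal(m$lambda, ref$lambda)))
      stop("models must share shape, lag window and lambda")
  }
  out <- ref
  out$weights <- Reduce(`+`, lapply(models, `[[`, "weights")) / length(models)
  out$intercept <- Reduce(`+`, lapply(models, `[[`, "intercept")) / length(models)
  out
}

#' Predict EEG from a TRF model
#'
#' Convolves the stimulus representation with the model weights (via the
#' lagged design, with the same zero-padding convention as fitting) and adds
#' the intercept.
#'
#' @param object A `trf_model`.
#' @param rep A [stim_rep()] whose features (labels) match the model's.
#' @param ... Unused.
#' @return Numeric time x channels matrix of predicted EEG.
#' @export
predict.trf_model <- function(object, rep, ...) {
  if (!identical(colnames(rep), object$feature_labels))
    stop("representation features do not match the model's")
  X <- lagged_design(rep, object$window)
  d <- dim(object$weights)
  wmat <- rbind(matrix(object$weights, d[1] * d[2], d[3]),
                object$intercept)
  out <- X %*% wmat
  colnames(out) <- object$channel_labels
  out
}

#' Pre-stimulus baseline correction of a TRF
#'
#' Subtracts, per feature and channel, the mean weight over the pre-stimulus
#' lag interval (default -20 to 0 ms), referencing each TRF trace to its own
#' pre-stimulus level before peak analysis or grand averaging.
#'
#' @param model A `trf_model` whose lag window covers `[t0, t1]`.
#' @param t0,t1 Baseline interval in ms.
#' @return A `trf_model` whose mean over `[t0, t1]` is zero for every
#'   feature/channel trace.
#' @export
baseline_correct <- function(model, t0 = -20, t1 = 0) {
  times <- model$window$times_ms
  idx <- which(times >= t0 & times <= t1)
  if (!length(idx) || t0 < model$window$tmin || t1 > model$window$tmax)
    stop("lag window does not cover the baseline interval")
  base <- colMeans(model$weights[idx, , , drop = FALSE])  # features x channels
  model$weights <- sweep(model$weights, c(2, 3), base, `-`)
  model
}

#' Fit a dataset-average TRF at a fixed lambda
#'
#' Fits a single-trial TRF to every trial and averages them: the "subject
#' TRF" used for visualisation and peak analysis. For repeated-stimulus
#' datasets the shared design is factorised once.
#'
#' @param data A [trf_dataset()].
#' @param recipe Function mapping an [envelope()] to a [stim_rep()].
#' @param window A [lag_window()].
#' @param lambda Ridge parameter.
#' @return A `trf_model`.
#' @export
trf_fit_dataset <- function(data, recipe, window, lambda) {
  M <- length(data$trials)
  repeated <- identical(data$stimulus_mode, "repeated")
  X <- NULL; G <- NULL
  wsum <- NULL; isum <- 0
  for (j in seq_len(M)) {
    if (is.null(X) || !repeated) {
      X <- lagged_design(recipe(data$trials[[j]]$envelope), window)
      G <- crossprod(X)
    }
    wmat <- ridge_solve(G, crossprod(X, unclass(data$trials[[j]]$eeg)), lambda)
    wsum <- if (is.null(wsum)) wmat else wsum + wmat
  }
  rep1 <- recipe(data$trials[[1]]$envelope)
  make_trf(wsum / M, window, lambda, colnames(rep1),
           colnames(data$trials[[1]]$eeg))
}

#' Plot the per-feature traces of a TRF at one channel
#'
#' For an amplitude-binned model this draws one trace per amplitude bin with
#' a vertical offset between adjacent traces (cosmetic, configurable).
#'
#' @param x A `trf_model`.
#' @param channel Channel index or label (default 1).
#' @param offset Vertical offset between traces; default chosen from the
#'   weight range.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.trf_model <- function(x, channel = 1, offset = NULL, ...) {
  if (is.character(channel)) channel <- match(channel, x$channel_labels)
  w <- x$weights[, , channel, drop = FALSE][, , 1]
  w <- as.matrix(w)
  if (is.null(offset)) offset <- 1.2 * diff(range(w))
  shifted <- sweep(w, 2, (seq_len(ncol(w)) - 1) * offset, `+`)
  graphics::matplot(x$window$times_ms, shifted, type = "l", lty = 1,
                    xlab = "lag (ms)", ylab = "TRF weight (offset traces)", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
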