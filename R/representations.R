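#' Stimulus representation matrix
#'
#' A time-by-features numeric matrix carrying one column per stimulus feature
#' (one for the univariate envelope representations; B columns for the
#' amplitude-binned envelope; concatenations for combined models), with
#' feature labels and a sampling rate.
#'
#' @param matrix Numeric matrix, time in rows, features in columns. All
#'   entries must be finite.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of feature labels (one per column).
#' @return Object of class `"stim_rep"`.
#' @export
stim_rep <- function(matrix, fs, labels = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (ncol(matrix) < 1L) stop("a representation needs at least one feature")
  if (!all(is.finite(matrix))) stop("representation entries must be finite")
  if (is.null(labels)) labels <- paste0("f", seq_len(ncol(matrix)))
  if (length(labels) != ncol(matrix)) stop("one label per feature required")
  colnames(matrix) <- labels
  structure(matrix, fs = as.numeric(fs), class = "stim_rep")
}

#' @export
print.stim_rep <- function(x, ...) {
  cat(sprintf("<stim_rep> %d samples x %d features @ %g Hz: %s\n",
              nrow(x), ncol(x), attr(x, "fs"),
              paste(colnames(x), collapse = ", ")))
  invisible(x)
}

#' Treat an envelope as a univariate stimulus representation
#' @param env An [envelope()].
#' @param label Feature label.
#' @return A single-column [stim_rep()].
#' @export
as_stim_rep <- function(env, label = "envelope") {
  stim_rep(matrix(as.numeric(env), ncol = 1), sample_rate(env), label)
}

#' SPL (dB) transform of an envelope
#'
#' Expresses the envelope on a decibel scale, `20 * log10(v)`, the standard
#' sound-pressure-level mapping used to linearise the roughly logarithmic
#' amplitude-to-response-magnitude relationship of the auditory system.
#' Samples below the floor (including exact zeros) are clipped to `floor_db`.
#' The output may be negative, so the nonnegativity invariant of raw
#' envelopes is waived for it.
#'
#' @param env An [envelope()] with nonnegative values.
#' @param floor_db Clipping floor in dB (negative; default -80).
#' @return An [envelope()] on the dB scale (possibly negative values).
#' @export
spl_envelope <- function(env, floor_db = -80) {
  if (floor_db >= 0) stop("floor_db must be negative")
  v <- as.numeric(env)
  if (any(v < 0)) stop("SPL transform expects a nonnegative envelope")
  lo <- 10^(floor_db / 20)
  out <- ifelse(v < lo, floor_db, 20 * log10(pmax(v, lo)))
  envelope(out, sample_rate(env), nonnegative = FALSE)
}

#' Onset envelope: half-wave-rectified first derivative
#'
#' Emphasises energy increases: `max(0, v[t] - v[t-1])` with the first sample
#' set to 0. Many auditory neurons respond preferentially to onsets, and an
#' onset representation captures response variance the raw envelope misses.
#'
#' @param env An [envelope()].
#' @return An [envelope()] of the same length and rate.
#' @export
onset_envelope <- function(env) {
  v <- as.numeric(env)
  d <- c(0, diff(v))
  envelope(pmax(d, 0), sample_rate(env))
}

#' Offset envelope: rectified negative first derivative
#'
#' Complement of [onset_envelope()]: `max(0, -(v[t] - v[t-1]))`, first sample
#' 0. `onset - offset` reconstructs the raw first difference exactly.
#'
#' @inheritParams onset_envelope
#' @return An [envelope()] of the same length and rate.
#' @export
offset_envelope <- function(env) {
  v <- as.numeric(env)
  d <- c(0, diff(v))
  envelope(pmax(-d, 0), sample_rate(env))
}

#' Derivative envelope: signed first difference
#' @inheritParams onset_envelope
#' @return An [envelope()] (signed; nonnegativity waived).
#' @export
derivative_envelope <- function(env) {
  v <- as.numeric(env)
  envelope(c(0, diff(v)), sample_rate(env), nonnegative = FALSE)
}

#' Logarithmic amplitude-binning scheme
#'
#' Builds the bin edges used to split a normalised envelope into logarithmic
#' amplitude bins of a fixed dB width. Raw interior edges are
#' `10^(k * width_db / 20)` for `k = 1 .. n_bins - 1`, with 0 prepended and
#' the top edge `10^(n_bins * width_db / 20)` appended; the whole range is
#' then rescaled affinely to `[0, 1]`, so the edges apply directly to an
#' envelope normalised by its global maximum. The lower anchor is 0, so the
#' lowest bin absorbs everything below the first dB edge and the edges
#' partition `[0, 1]`.
#'
#' @param width_db Bin width in dB (default 8, the width at which prediction
#'   accuracy peaked in development of the method).
#' @param n_bins Number of bins B (default 8, spanning 64 dB).
#' @return Object of class `"ab_binning"`: list with `width_db`, `n_bins`,
#'   `edges` (length B + 1, strictly increasing, first 0, last 1).
#' @examples
#' db_binning(8, 8)$edges
#' @export
db_binning <- function(width_db = 8, n_bins = 8) {
  if (width_db <= 0) stop("width_db must be positive")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  raw <- c(0, 10^((seq_len(n_bins)) * width_db / 20))
  structure(list(width_db = width_db, n_bins = n_bins,
                 edges = raw / raw[n_bins + 1L]),
            class = "ab_binning")
}

#' @export
print.ab_binning <- function(x, ...) {
  cat(sprintf("<ab_binning> %d bins of %g dB; edges: %s\n", x$n_bins,
              x$width_db, paste(signif(x$edges, 4), collapse = " ")))
  invisible(x)
}

#' Amplitude-binned (AB) envelope representation
#'
#' Splits the envelope into B sub-envelopes covering different amplitude
#' ranges. The envelope is first rescaled to `[0, 1]` by dividing by `scale`
#' (by default its own maximum; pass the corpus-wide maximum when binning
#' several trials so all share one scale). Each sample is assigned to exactly
#' one bin by half-open membership `[edge_b, edge_{b+1})` (top bin closed),
#' and within its bin is mapped affinely onto `[0, 1]` using the bin's own
#' edges. The affine map is invertible, so the binned representation is a
#' lossless coding of the rescaled envelope; the per-bin normalisation is
#' what keeps the multivariate TRF fit stable.
#'
#' @param env An [envelope()] with nonnegative values, not all zero.
#' @param binning An [db_binning()] scheme.
#' @param scale Positive divisor mapping the envelope into `[0, 1]`;
#'   default `max(env)`.
#' @return A [stim_rep()] with B columns labelled `bin1` (lowest amplitude)
#'   to `binB`. At each time sample at most one column is nonzero, and all
#'   entries lie in `[0, 1]`.
#' @export
ab_envelope <- function(env, binning = db_binning(), scale = NULL) {
  v <- as.numeric(env)
  if (any(v < 0)) stop("amplitude binning expects a nonnegative envelope")
  if (max(v) == 0) stop("all-zero envelope has no dynamic range to bin")
  if (is.null(scale)) scale <- max(v)
  if (scale <= 0) stop("scale must be positive")
  v <- pmin(v / scale, 1)
  e <- binning$edges
  B <- binning$n_bins
  ## half-open [lo, hi) bins, top bin closed
  idx <- findInterval(v, e, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > B] <- B
  out <- matrix(0, length(v), B)
  val <- (v - e[idx]) / (e[idx + 1L] - e[idx])
  out[cbind(seq_along(v), idx)] <- val
  stim_rep(out, sample_rate(env), paste0("bin", seq_len(B)))
}

#' Invert an amplitude-binned representation
#'
#' Recovers the rescaled (`[0, 1]`) envelope from its binned coding by
#' applying the inverse affine map in each sample's active bin. Exact up to
#' machine precision; mostly useful for verification.
#'
#' @param rep A [stim_rep()] produced by [ab_envelope()].
#' @param binning The [db_binning()] used to produce it.
#' @return An [envelope()] with values in `[0, 1]`.
#' @export
ab_invert <- function(rep, binning) {
  e <- binning$edges
  B <- binning$n_bins
  if (ncol(rep) != B) stop("representation/binning mismatch")
  m <- unclass(rep)
  active <- max.col(m != 0, ties.method = "first")
  any_active <- rowSums(m != 0) > 0
  v <- numeric(nrow(m))
  a <- active[any_active]
  v[any_active] <- e[a] + m[cbind(which(any_active), a)] * (e[a + 1L] - e[a])
  ## samples exactly at a bin's lower edge code as all-zero rows; they decode
  ## to 0, which is exact for the (measure-one) case of the bottom edge
  envelope(v, sample_rate(rep))
}

#' Concatenate stimulus representations feature-wise
#'
#' Combines representations (e.g. the AB envelope plus the onset envelope)
#' into one multivariate representation for a combined TRF model.
#'
#' @param ... [stim_rep()] objects with identical lengths and sampling rates.
#' @return A [stim_rep()] whose columns and labels are the concatenation of
#'   the inputs'.
#' @export
concat_reps <- function(...) {
  reps <- list(...)
  if (length(reps) == 1L && is.list(reps[[1]]) && !inherits(reps[[1]], "stim_rep"))
    reps <- reps[[1]]
  if (!length(reps)) stop("no representations given")
  fs <- sample_rate(reps[[1]])
  n <- nrow(reps[[1]])
  for (r in reps) {
    if (nrow(r) != n || !isTRUE(all.equal(sample_rate(r), fs)))
      stop("representations must share length and sampling rate")
  }
  stim_rep(do.call(cbind, lapply(reps, unclass)), fs,
           unlist(lapply(reps, colnames)))
}
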