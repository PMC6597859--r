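#' Circularly shift a vector
#'
#' `y[t] = x[(t - s - 1) mod n + 1]`: the series is rotated so that what
#' happened at time 1 happens at time `s + 1`, with wrap-around. Shifts of 0
#' or multiples of the length are the identity.
#'
#' @param x Numeric vector.
#' @param s Integer shift in samples (any sign).
#' @return Shifted vector of the same length.
#' @export
circular_shift <- function(x, s) {
  n <- length(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(x)
  c(x[(n - s + 1L):n], x[1:(n - s)])
}

#' Pool of circularly shifted envelopes
#'
#' For a repeated-stimulus dataset with M trials, the null pool consists of
#' the original envelope plus M - 1 copies, each shifted by a further
#' `1/M` of the envelope length (shifts `floor(k * L / M)` samples,
#' k = 0 .. M-1).
#'
#' @param env An [envelope()].
#' @param m Pool size.
#' @return List of `m` envelopes.
#' @export
shift_pool <- function(env, m) {
  L <- length(env)
  fs <- sample_rate(env)
  lapply(0:(m - 1L), function(k)
    envelope(circular_shift(as.numeric(env), floor(k * L / m)), fs,
             nonnegative = FALSE))
}

#' Permutation null distribution of model accuracy
#'
#' Destroys stimulus-response alignment and reruns the full nested
#' cross-validation to obtain the distribution of accuracies expected by
#' chance. For repeated-stimulus data, a pool of M circularly shifted copies
#' of the single envelope is built (see [shift_pool()]) and each repetition
#' draws M envelopes from the pool with replacement. For distinct-stimulus
#' data, each repetition reassigns the original envelopes to trials at random
#' with replacement. The null threshold is the maximum accuracy over
#' repetitions.
#'
#' @param data A [trf_dataset()].
#' @param recipe Function mapping an [envelope()] to a [stim_rep()].
#' @param window A [lag_window()].
#' @param lambda_grid Ridge grid, as in [nested_cv()].
#' @param n_reps Number of repetitions (default 100).
#' @param seed Master seed; per-repetition seeds are fanned out from it and
#'   recorded in the result.
#' @param channels Optional channel subset for accuracy averaging.
#' @param mode Null construction; defaults to the dataset's `stimulus_mode`.
#'   Requesting `"repeated"` on distinct-stimulus data is an error.
#' @return Object of class `"trf_null"`: list with `accuracies` (length
#'   `n_reps`), `threshold` (their maximum), `mode`, `seed`, `rep_seeds`.
#' @export
permutation_null <- function(data, recipe, window,
                             lambda_grid = default_lambda_grid(),
                             n_reps = 100, seed = 1, channels = NULL,
                             mode = data$stimulus_mode) {
  mode <- match.arg(mode, c("repeated", "distinct"))
  if (mode == "repeated" && data$stimulus_mode != "repeated")
    stop("circular-shift null requires a repeated-stimulus dataset")
  M <- length(data$trials)
  pool_envs <- if (mode == "repeated")
    shift_pool(data$trials[[1]]$envelope, M)
  else
    lapply(data$trials, `[[`, "envelope")

  ## pool designs and all pool x trial cross-moments, computed once
  Xs <- lapply(pool_envs, function(e) lagged_design(recipe(e), window))
  Gs <- lapply(Xs, crossprod)
  Ys <- lapply(data$trials, function(tr) unclass(tr$eeg))
  H <- lapply(seq_len(M), function(k)
    lapply(seq_len(M), function(j) crossprod(Xs[[k]], Ys[[j]])))
  ysum <- lapply(Ys, colSums)
  yy <- lapply(Ys, function(y) colSums(y^2))
  ns <- vapply(Ys, nrow, integer(1))

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  acc <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    a <- sample.int(M, M, replace = TRUE)
    stats <- lapply(seq_len(M), function(j)
      list(G = Gs[[a[j]]], H = H[[a[j]]][[j]], ysum = ysum[[j]],
           yy = yy[[j]], n = ns[j], design_id = a[j]))
    acc[r] <- cv_from_stats(stats, lambda_grid, channels,
                            colnames(data$trials[[1]]$eeg))$overall
  }
  structure(list(accuracies = acc, threshold = max(acc), mode = mode,
                 seed = seed, rep_seeds = rep_seeds, n_reps = n_reps),
            class = "trf_null")
}

#' @export
print.trf_null <- function(x, ...) {
  cat(sprintf("<trf_null> %d reps (%s mode): mean %.4f, max (threshold) %.4f\n",
              x$n_reps, x$mode, mean(x$accuracies), x$threshold))
  invisible(x)
}

#' Compare observed accuracies against a permutation null
#'
#' Reports both criteria in common use: a one-sample t test of the
#' per-subject accuracies against the null-distribution mean, and the
#' stricter requirement that every observed accuracy exceed the maximum of
#' the null distribution.
#'
#' @param accuracies Numeric vector of observed per-subject accuracies.
#' @param null A `trf_null`.
#' @return List with `t`, `p` (one-sample test vs the null mean),
#'   `above_max` (logical: all observations beat the null maximum),
#'   `null_mean`, `null_max`.
#' @export
above_null <- function(accuracies, null) {
  tt <- stats::t.test(accuracies, mu = mean(null$accuracies),
                      alternative = "greater")
  list(t = unname(tt$statistic), p = tt$p.value,
       above_max = all(accuracies > null$threshold),
       null_mean = mean(null$accuracies), null_max = null$threshold)
}
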