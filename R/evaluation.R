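#' Dataset of paired stimulus envelopes and EEG trials
#'
#' @param trials List of length M (M >= 3; nested cross-validation needs
#'   train/validation/test) where each element is a list with components
#'   `envelope` (an [envelope()]) and `eeg` (an [eeg_trial()]).
#' @param fs Common sampling rate in Hz.
#' @param stimulus_mode `"repeated"` (one stimulus repeated every trial, as
#'   in an AM-noise design) or `"distinct"` (different stimulus per trial, as
#'   in continuous speech). Controls the permutation-null construction and
#'   enables design reuse.
#' @return Object of class `"trf_dataset"`.
#' @export
trf_dataset <- function(trials, fs, stimulus_mode = c("repeated", "distinct")) {
  stimulus_mode <- match.arg(stimulus_mode)
  if (length(trials) < 3L) stop("nested cross-validation needs at least 3 trials")
  for (tr in trials) {
    if (!inherits(tr$envelope, "envelope") || !inherits(tr$eeg, "eeg_trial"))
      stop("each trial must hold an envelope and an eeg_trial")
    if (!isTRUE(all.equal(sample_rate(tr$envelope), fs)) ||
        !isTRUE(all.equal(sample_rate(tr$eeg), fs)))
      stop("all trials must share the dataset sampling rate")
  }
  structure(list(trials = trials, fs = fs, stimulus_mode = stimulus_mode),
            class = "trf_dataset")
}

#' @export
print.trf_dataset <- function(x, ...) {
  cat(sprintf("<trf_dataset> %d trials @ %g Hz (%s stimulus), %d channels\n",
              length(x$trials), x$fs, x$stimulus_mode,
              ncol(x$trials[[1]]$eeg)))
  invisible(x)
}

#' Per-channel Pearson prediction accuracy
#'
#' The standard accuracy metric for forward encoding models: Pearson's r
#' between predicted and recorded EEG, per channel, over the full trial.
#'
#' @param pred,actual Numeric time x channels matrices of equal shape.
#' @return Numeric vector of r values (one per channel). A zero-variance
#'   channel yields `NA` and is excluded from downstream averages.
#' @export
pearson_accuracy <- function(pred, actual) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  if (!identical(dim(pred), dim(actual))) stop("shape mismatch")
  r <- vapply(seq_len(ncol(pred)), function(j) {
    if (stats::sd(pred[, j]) == 0 || stats::sd(actual[, j]) == 0) return(NA_real_)
    stats::cor(pred[, j], actual[, j])
  }, numeric(1))
  names(r) <- colnames(actual)
  r
}

## Sufficient statistics of one trial for ridge fitting and correlation
## scoring: X'X, X'Y, per-channel sums and sums of squares of Y. All CV and
## permutation computation runs on these, never on materialised predictions
## (algebraically identical; see tests).
trial_stats <- function(X, Y, design_id = 1L) {
  list(G = crossprod(X), H = crossprod(X, Y),
       ysum = colSums(Y), yy = colSums(Y^2),
       n = nrow(X), design_id = design_id)
}

## Pearson r per channel of prediction X w against y, assembled from Gram
## statistics: needs q = X'1, w'Gw, w'X'y and the y moments.
pearson_from_stats <- function(W, GW, st) {
  p <- nrow(W)
  sp <- colSums(st$G[, p] * W)           # sum of predictions (q = X'1)
  spp <- colSums(W * GW)                 # sum of squared predictions
  spy <- colSums(W * st$H)               # sum pred * y
  n <- st$n
  varp <- n * spp - sp^2
  vary <- n * st$yy - st$ysum^2
  den2 <- varp * vary
  r <- rep(NA_real_, length(spy))
  ok <- is.finite(den2) & den2 > 0
  r[ok] <- ((n * spy - sp * st$ysum)[ok]) / sqrt(den2[ok])
  rss <- st$yy - 2 * spy + spp
  list(r = r, rss = rss)
}

## Core nested leave-one-out CV on precomputed per-trial statistics.
## Per outer test trial t: every remaining trial v serves once as validation;
## per lambda the M-2 single-trial training models are averaged and scored on
## v; lambda maximising the validation accuracy (averaged over inner folds
## and the selection channel set) is chosen; the average of the M-1
## non-test models at that lambda is scored on t.
cv_from_stats <- function(stats, lambda_grid, channels = NULL,
                          channel_labels = NULL) {
  M <- length(stats)
  if (M < 3L) stop("nested cross-validation needs at least 3 trials")
  if (!length(lambda_grid)) stop("empty lambda grid")
  p <- nrow(stats[[1]]$G)
  C <- ncol(stats[[1]]$H)
  if (is.null(channels)) channels <- seq_len(C)
  nl <- length(lambda_grid)
  design_ids <- vapply(stats, `[[`, integer(1), "design_id")

  inner <- array(NA_real_, c(M, M, nl, C))  # [test t, validation v, lambda, ch]
  test_raw <- array(NA_real_, c(M, nl, C))
  rss_raw <- array(NA_real_, c(M, nl, C))

  for (li in seq_len(nl)) {
    lam <- lambda_grid[li]
    ## single-trial weights; Cholesky factor shared across trials with the
    ## same design (repeated-stimulus datasets, permutation pools)
    Warr <- array(0, c(p, C, M))
    chol_cache <- list()
    for (i in seq_len(M)) {
      key <- as.character(design_ids[i])
      R <- chol_cache[[key]]
      if (is.null(R)) {
        G <- stats[[i]]$G
        A <- G
        if (lam > 0) {
          idx <- seq_len(p - 1L)
          A[cbind(idx, idx)] <- A[cbind(idx, idx)] + lam * mean(diag(G)[-p])
        }
        R <- tryCatch(chol(A), error = function(e)
          stop(sprintf("rank-deficient fit for trial %d at lambda = %g", i, lam),
               call. = FALSE))
        chol_cache[[key]] <- R
      }
      Warr[, , i] <- backsolve(R, backsolve(R, stats[[i]]$H, transpose = TRUE))
    }
    Wsum <- rowSums(Warr, dims = 2)
    Wcat <- matrix(Warr, p, C * M)

    for (d in unique(design_ids)) {
      members <- which(design_ids == d)
      Gd <- stats[[members[1]]]$G
      Barr <- array(Gd %*% Wcat, c(p, C, M))
      Bsum <- rowSums(Barr, dims = 2)
      for (v in members) {
        st <- stats[[v]]
        ## outer-fold test score for fold v: average of all non-test models
        Wbar <- (Wsum - Warr[, , v]) / (M - 1)
        GW <- (Bsum - Barr[, , v]) / (M - 1)
        sc <- pearson_from_stats(Wbar, GW, st)
        test_raw[v, li, ] <- sc$r
        rss_raw[v, li, ] <- sc$rss
        ## inner validation scores: v validates fold t for every t != v
        for (t in seq_len(M)[-v]) {
          Wbar <- (Wsum - Warr[, , t] - Warr[, , v]) / (M - 2)
          GW <- (Bsum - Barr[, , t] - Barr[, , v]) / (M - 2)
          inner[t, v, li, ] <- pearson_from_stats(Wbar, GW, st)$r
        }
      }
    }
  }

  lambda_idx <- integer(M)
  test_acc <- matrix(NA_real_, M, C, dimnames = list(NULL, channel_labels))
  test_rss <- matrix(NA_real_, M, C)
  for (t in seq_len(M)) {
    score <- vapply(seq_len(nl), function(li)
      mean(inner[t, -t, li, channels], na.rm = TRUE), numeric(1))
    lambda_idx[t] <- which.max(score)  # ties resolve to the smaller lambda
    test_acc[t, ] <- test_raw[t, lambda_idx[t], ]
    test_rss[t, ] <- rss_raw[t, lambda_idx[t], ]
  }

  structure(list(
    inner_accuracies = inner,
    test_accuracies = test_acc,
    test_rss = test_rss,
    lambda_grid = lambda_grid,
    lambda_index = lambda_idx,
    lambda_selected = lambda_grid[lambda_idx],
    channels = channels,
    channel_labels = channel_labels,
    n_params = p,
    n_per_trial = vapply(stats, `[[`, numeric(1), "n"),
    overall = mean(test_acc[, channels], na.rm = TRUE)
  ), class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("<trf_cv> %d outer folds, overall accuracy r = %.4f (lambda: %s)\n",
              nrow(x$test_accuracies), x$overall,
              paste(signif(unique(x$lambda_selected), 3), collapse = ", ")))
  invisible(x)
}

#' Default ridge parameter grid
#'
#' Logarithmic grid spanning effectively unregularised to heavily shrunk
#' fits. Because the penalty is rescaled by the design's diagonal power, one
#' grid serves all representations.
#' @return Numeric vector of lambda values.
#' @export
default_lambda_grid <- function() 10^seq(-6, 4, by = 2)

#' Nested leave-one-out cross-validation of a TRF model
#'
#' For each outer fold one trial is held out as the test set. Within the
#' remaining M-1 trials, each serves once as validation: per ridge parameter,
#' the M-2 single-trial models of the training set are averaged and used to
#' predict the validation trial, scored by Pearson's r. The lambda with the
#' best validation accuracy (averaged over inner folds and the selection
#' channel set) is then used to score the average of all M-1 non-test models
#' on the test trial. Every trial is tested exactly once; overall accuracy is
#' the mean test r over folds and (selection) channels.
#'
#' @param data A [trf_dataset()].
#' @param recipe Function mapping an [envelope()] to a [stim_rep()] (see
#'   [stimulus_recipes()]).
#' @param window A [lag_window()].
#' @param lambda_grid Nonempty numeric vector of ridge parameters.
#' @param channels Optional integer vector of channel indices over which
#'   lambda selection and the overall accuracy are averaged (e.g. the output
#'   of [select_channels()] on the envelope model). Default: all channels.
#' @return Object of class `"trf_cv"`: per-fold/channel test accuracies and
#'   residual sums of squares, the full inner accuracy array
#'   (test x validation x lambda x channel), selected lambdas, and `overall`.
#' @export
nested_cv <- function(data, recipe, window, lambda_grid = default_lambda_grid(),
                      channels = NULL) {
  M <- length(data$trials)
  repeated <- identical(data$stimulus_mode, "repeated")
  stats <- vector("list", M)
  X <- NULL
  for (j in seq_len(M)) {
    if (is.null(X) || !repeated) {
      rep_j <- recipe(data$trials[[j]]$envelope)
      X <- lagged_design(rep_j, window)
    }
    stats[[j]] <- trial_stats(X, unclass(data$trials[[j]]$eeg),
                              design_id = if (repeated) 1L else j)
  }
  cv_from_stats(stats, lambda_grid, channels,
                colnames(data$trials[[1]]$eeg))
}

#' Select the best-predicted channels from a reference model
#'
#' Returns the indices of the `n` channels with the highest mean test
#' accuracy in the reference cross-validation result (conventionally the
#' plain envelope model). Ties resolve deterministically to the lower channel
#' index. Model comparisons then average accuracy over this fixed set.
#'
#' @param reference A `trf_cv`.
#' @param n Number of channels to keep (e.g. 7 of a 32-channel montage).
#' @return Integer vector of channel indices, ordered by decreasing accuracy.
#' @export
select_channels <- function(reference, n) {
  m <- colMeans(reference$test_accuracies, na.rm = TRUE)
  if (n > length(m)) stop("n exceeds the channel count")
  order(-m, seq_along(m))[seq_len(n)]
}

#' Akaike information criterion for a prediction
#'
#' Gaussian-likelihood AIC, `n * log(RSS / n) + 2k`, computed per channel.
#' Used for model comparisons that must discount the larger parameter count
#' of multivariate representations. `k` is the total weight count of the
#' model (lags x features + intercept).
#'
#' @param pred,actual Numeric time x channels matrices of equal shape.
#' @param k Parameter count (>= 1).
#' @return Numeric vector, one AIC per channel (`-Inf` if the fit is exact).
#' @export
aic_score <- function(pred, actual, k) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  if (!identical(dim(pred), dim(actual))) stop("shape mismatch")
  if (k < 1) stop("k must be at least 1")
  n <- nrow(pred)
  rss <- colSums((actual - pred)^2)
  ifelse(rss == 0, -Inf, n * log(rss / n) + 2 * k)
}

#' AIC of a cross-validated model on its test folds
#'
#' Applies the [aic_score()] formula to the stored test-fold residuals of a
#' `trf_cv`, averaging over folds and the given channels.
#'
#' @param cv A `trf_cv`.
#' @param channels Channel indices (default: the cv's selection set).
#' @return Scalar mean AIC.
#' @export
cv_aic <- function(cv, channels = cv$channels) {
  k <- cv$n_params
  n <- cv$n_per_trial
  a <- cv$test_rss[, channels, drop = FALSE]
  aic <- n * log(a / n) + 2 * k  # n recycles down rows (folds)
  aic[a == 0] <- -Inf
  mean(aic, na.rm = TRUE)
}

#' Paired effect size from a t statistic
#'
#' Cohen's d for a paired-sample t test, `d = t / sqrt(n)` with n the number
#' of paired observations (subjects).
#'
#' @param t t statistic.
#' @param n Number of pairs (>= 1).
#' @return Effect size d.
#' @examples
#' cohens_d(4.800, 13)  # 1.331
#' @export
cohens_d <- function(t, n) {
  if (n < 1) stop("n must be at least 1")
  t / sqrt(n)
}

#' Paired comparison of two models' per-subject accuracies
#'
#' Two-sided paired t test with Cohen's d (`t / sqrt(n)`), a Wilcoxon
#' signed-rank test as the distribution-free fallback, and Anderson-Darling
#' normality checks of each accuracy vector (requires n >= 8; reported as
#' `NA` otherwise).
#'
#' @param acc_a,acc_b Equal-length numeric vectors (n >= 3) of per-subject
#'   accuracies for models A and B.
#' @return Object of class `"trf_comparison"`: list with `t`, `p`, `d`,
#'   `wilcoxon_p`, `normal_a`, `normal_b` (Anderson-Darling p values),
#'   `normality_ok`, `n`, `mean_diff`, `degenerate`.
#' @export
paired_comparison <- function(acc_a, acc_b) {
  n <- length(acc_a)
  if (length(acc_b) != n) stop("accuracy vectors must have equal length")
  if (n < 3L) stop("need at least 3 paired observations")
  diffs <- acc_a - acc_b
  degenerate <- stats::sd(diffs) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
    wp <- NA_real_
  } else {
    tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
    wp <- suppressWarnings(
      stats::wilcox.test(acc_a, acc_b, paired = TRUE, exact = FALSE)$p.value)
  }
  ad <- function(x) if (length(x) >= 8) tryCatch(nortest::ad.test(x)$p.value,
                                                 error = function(e) NA_real_)
                    else NA_real_
  na <- ad(acc_a); nb <- ad(acc_b)
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 d = if (is.na(tt$statistic[1])) NA_real_
                     else cohens_d(unname(tt$statistic), n),
                 wilcoxon_p = wp, normal_a = na, normal_b = nb,
                 normality_ok = if (is.na(na) || is.na(nb)) NA
                                else na > 0.05 && nb > 0.05,
                 n = n, mean_diff = mean(diffs), degenerate = degenerate),
            class = "trf_comparison")
}

#' @export
print.trf_comparison <- function(x, ...) {
  cat(sprintf("<trf_comparison> n = %d: t = %.3f, p = %.3g, d = %.3f; Wilcoxon p = %.3g\n",
              x$n, x$t, x$p, x$d, x$wilcoxon_p))
  if (isFALSE(x$normality_ok))
    cat("  note: Anderson-Darling rejects normality; prefer the Wilcoxon p\n")
  invisible(x)
}
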