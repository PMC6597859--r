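test_that("lagged design unrolls the convolution with zero padding", {
  e <- envelope(c(0.1, 0.7, 0.3, 0.9, 0.2, 0.5, 0.4, 0.8, 0.6, 0.35), 1000)
  r <- as_stim_rep(e)
  # lags {0}: the design is the feature itself plus an intercept
  w0 <- lag_window(0, 0.4, 1000)  # single lag at 0 ms
  X <- lagged_design(r, w0)
  expect_equal(ncol(X), 2)
  expect_equal(X[, 1], as.numeric(e))
  expect_equal(X[, 2], rep(1, 10))
})

test_that("a unit impulse probes each lag column", {
  imp <- numeric(20); imp[5] <- 1
  r <- stim_rep(matrix(imp, ncol = 1), 1000, "x")
  w <- lag_window(0, 3, 1000)  # lags 0..3 samples
  X <- lagged_design(r, w)
  for (j in 1:4) {
    expected <- numeric(20); expected[5 + (j - 1)] <- 1
    expect_equal(X[, j], expected)
  }
  # negative lags shift the other way
  wn <- lag_window(-2, 0, 1000)
  Xn <- lagged_design(r, wn)
  expect_equal(which(Xn[, 1] == 1), 3)  # lag -2
})

test_that("design of concatenated reps equals column-concatenated designs", {
  set.seed(7)
  e <- envelope(stats::runif(100), 128)
  a <- ab_envelope(e, db_binning(8, 4))
  b <- as_stim_rep(onset_envelope(e), "onset")
  w <- lag_window(-30, 60, 128)
  Xab <- lagged_design(concat_reps(a, b), w)
  Xa <- lagged_design(a, w); Xb <- lagged_design(b, w)
  p_a <- ncol(Xa) - 1
  expect_equal(Xab, cbind(Xa[, 1:p_a], Xb))  # shared trailing intercept
})

test_that("noiseless convolution is inverted by the unregularised fit", {
  set.seed(8)
  fs <- 128
  kern <- c(0.5, 1, -2, 0.7, 0.1)
  x <- stats::runif(600)
  y <- numeric(600)
  for (l in 0:4) y[(l + 1):600] <- y[(l + 1):600] + kern[l + 1] * x[1:(600 - l)]
  r <- stim_rep(matrix(x, ncol = 1), fs, "x")
  eeg <- eeg_trial(matrix(y, ncol = 1), fs)
  w <- lag_window(0, 4 / fs * 1000, fs)
  fit <- trf_fit(r, eeg, w, lambda = 0)
  expect_equal(as.numeric(fit$weights[, 1, 1]), kern, tolerance = 1e-6)
  expect_lt(abs(fit$intercept[1]), 1e-8)
})

test_that("extreme regularisation shrinks all penalised weights to zero", {
  set.seed(9)
  r <- stim_rep(matrix(stats::rnorm(300), ncol = 1), 128, "x")
  eeg <- eeg_trial(matrix(stats::rnorm(300), ncol = 1), 128)
  fit <- trf_fit(r, eeg, lag_window(-50, 100, 128), lambda = 1e12)
  expect_lt(max(abs(fit$weights)), 1e-6)
})

test_that("ridge solution matches a dense normal-equation oracle", {
  set.seed(10)
  e <- envelope(stats::runif(200), 128)
  rep2 <- concat_reps(ab_envelope(e, db_binning(8, 3)),
                      as_stim_rep(onset_envelope(e), "onset"))
  eeg <- eeg_trial(matrix(stats::rnorm(400), 200, 2), 128)
  w <- lag_window(-30, 80, 128)
  X <- lagged_design(rep2, w)
  for (lam in c(1e-3, 1, 100)) {
    fit <- trf_fit(rep2, eeg, w, lam)
    W <- ridge_oracle(X, unclass(eeg), lam)
    d <- dim(fit$weights)
    got <- rbind(matrix(fit$weights, d[1] * d[2], d[3]), fit$intercept)
    expect_lt(max(abs(got - W)), 1e-8)
  }
})

test_that("model averaging is the elementwise mean", {
  set.seed(11)
  r <- stim_rep(matrix(stats::runif(150), ncol = 1), 128, "x")
  w <- lag_window(0, 50, 128)
  ms <- lapply(1:3, function(i)
    trf_fit(r, eeg_trial(matrix(stats::rnorm(150), ncol = 1), 128), w, 1))
  avg <- trf_average(ms)
  expect_equal(avg$weights,
               (ms[[1]]$weights + ms[[2]]$weights + ms[[3]]$weights) / 3)
  expect_equal(trf_average(list(ms[[1]], ms[[1]]))$weights, ms[[1]]$weights)
  neg <- ms[[1]]; neg$weights <- -neg$weights; neg$intercept <- -neg$intercept
  zero <- trf_average(list(ms[[1]], neg))
  expect_equal(max(abs(zero$weights)), 0)
})

test_that("prediction is consistent, linear and label-checked", {
  set.seed(12)
  e <- envelope(stats::runif(400), 128)
  r <- ab_envelope(e, db_binning(8, 4))
  w <- lag_window(-50, 150, 128)
  # noiseless generative responses: y = X w_true
  X <- lagged_design(r, w)
  eeg <- eeg_trial(X %*% matrix(stats::rnorm(2 * ncol(X)), ncol(X), 2), 128)
  fit <- trf_fit(r, eeg, w, 0)
  pred <- predict(fit, r)
  expect_true(all(pearson_accuracy(pred, eeg) > 0.999))
  # zero model gives a zero prediction
  z <- fit; z$weights[] <- 0; z$intercept[] <- 0
  expect_equal(max(abs(predict(z, r))), 0)
  # linearity in the input for single-feature models without intercept
  r1 <- as_stim_rep(e); r2 <- as_stim_rep(onset_envelope(e))
  f1 <- trf_fit(r1, eeg, w, 1); f1$intercept[] <- 0
  mix <- stim_rep(2 * unclass(r1) - 3 * unclass(r2), 128, "envelope")
  expect_equal(predict(f1, mix),
               2 * predict(f1, r1) - 3 * predict(f1, stim_rep(unclass(r2), 128, "envelope")),
               tolerance = 1e-10)
  bad <- r; colnames(bad) <- paste0("other", 1:4)
  expect_error(predict(fit, bad), "match")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  set.seed(13)
  r <- as_stim_rep(envelope(stats::runif(300), 128))
  eeg <- eeg_trial(matrix(stats::rnorm(600), 300, 2), 128)
  w <- lag_window(-100, 300, 128)
  fit <- trf_fit(r, eeg, w, 1)
  cor1 <- baseline_correct(fit)
  idx <- which(w$times_ms >= -20 & w$times_ms <= 0)
  expect_lt(max(abs(colMeans(cor1$weights[idx, , , drop = FALSE]))), 1e-12)
  # already zero-mean -> unchanged; constant weights -> all zero
  expect_equal(baseline_correct(cor1)$weights, cor1$weights)
  const <- fit; const$weights[] <- 2.5
  expect_equal(max(abs(baseline_correct(const)$weights)), 0)
  expect_error(baseline_correct(fit, -500, -400), "cover")
})

test_that("weight tensor layout round-trips through flatten/reshape", {
  set.seed(14)
  e <- envelope(stats::runif(200), 128)
  r <- ab_envelope(e, db_binning(8, 3))
  eeg <- eeg_trial(matrix(stats::rnorm(400), 200, 2), 128)
  w <- lag_window(0, 100, 128)
  fit <- trf_fit(r, eeg, w, 0.1)
  # manual per-feature convolution must equal predict()
  pred <- predict(fit, r)
  manual <- matrix(rep(fit$intercept, each = 200), 200, 2)
  lags <- w$lags
  for (f in 1:3) for (ch in 1:2) {
    acc <- numeric(200)
    for (j in seq_along(lags)) {
      l <- lags[j]
      if (l >= 0) acc[(l + 1):200] <- acc[(l + 1):200] +
          fit$weights[j, f, ch] * unclass(r)[1:(200 - l), f]
    }
    manual[, ch] <- manual[, ch] + acc
  }
  expect_equal(pred, manual, ignore_attr = TRUE, tolerance = 1e-12)
})
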