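mk_trace <- function(times, f) vapply(times, f, numeric(1))

test_that("peak detection finds the dominant extremum with tie and fallback rules", {
  times <- seq(-100, 400, by = 1000 / 128)
  trough <- mk_trace(times, function(t) -exp(-(t - 150)^2 / 200))
  pk <- detect_peak(trough, times, c(70, 210), "negative")
  expect_lt(abs(pk$latency_ms - 150), 1000 / 128)
  expect_true(pk$local)
  # monotone ramp: no interior extremum, flagged endpoint returned
  ramp <- times / 100
  pk2 <- detect_peak(ramp, times, c(70, 210), "positive")
  expect_false(pk2$local)
  expect_equal(pk2$latency_ms, max(times[times <= 210]))
  # two exactly equal troughs resolve to the earliest
  t2 <- seq(0, 300, by = 10)
  two <- numeric(length(t2))
  two[t2 == 100] <- -1
  two[t2 == 180] <- -1
  pk3 <- detect_peak(two, t2, c(70, 210), "negative")
  expect_equal(pk3$latency_ms, 100)
  expect_true(pk3$local)
  expect_error(detect_peak(trough, times, c(300, 500), "negative"), "window")
})

test_that("peak detection is invariant to uniform scaling", {
  times <- seq(0, 300, by = 1000 / 128)
  tr <- mk_trace(times, function(t)
    exp(-(t - 60)^2 / 150) - 1.5 * exp(-(t - 140)^2 / 300))
  p1 <- detect_peak(tr, times, c(0, 130), "positive")
  p1s <- detect_peak(5 * tr, times, c(0, 130), "positive")
  expect_equal(p1s$latency_ms, p1$latency_ms)
  expect_equal(p1s$amplitude, 5 * p1$amplitude)
})

test_that("peak tables track per-bin structure and flag empty bins", {
  w <- lag_window(-100, 400, 128)
  times <- w$times_ms
  B <- 5
  weights <- array(0, c(length(times), B, 1))
  shift <- 12
  for (b in 1:B) {
    lat <- 140 + shift * (B - b)
    weights[, b, 1] <- mk_trace(times, function(t)
      0.2 * exp(-(t - 50)^2 / 150) - exp(-(t - lat)^2 / 250))
  }
  weights[, 2, 1] <- 0  # knock out one bin
  model <- structure(list(weights = weights, window = w, lambda = 0, fs = 128,
                          feature_labels = paste0("bin", 1:B),
                          channel_labels = "ch1", intercept = 0),
                     class = "trf_model")
  tab <- peak_table(model, 1)
  expect_true(tab$missing[2])
  expect_false(any(tab$missing[-2]))
  got <- tab$n1_latency[!tab$missing]
  want <- 140 + shift * (B - (1:B))[-2]
  expect_true(all(abs(got - want) < 1000 / 128))
  expect_true(all(tab$p1n1[!tab$missing] > 0))
  # identical kernels in all bins give constant latencies
  for (b in 1:B) weights[, b, 1] <- weights[, 1, 1]
  model$weights <- weights
  tab2 <- peak_table(model, 1)
  expect_equal(length(unique(tab2$n1_latency)), 1)
})

test_that("latency trend matches closed-form OLS and degrades under shuffling", {
  bins <- 1:8
  lat <- 200 - 11 * bins
  tab <- data.frame(bin = bins, n1_latency = lat)
  tr <- latency_trend(tab)
  expect_equal(tr$slope, -11, tolerance = 1e-10)
  expect_equal(tr$per_bin_decrease, 11, tolerance = 1e-10)
  expect_equal(tr$r_squared, 1, tolerance = 1e-10)
  # closed-form OLS oracle on noisy latencies
  set.seed(51)
  lat2 <- lat + stats::rnorm(8, sd = 4)
  tr2 <- latency_trend(data.frame(bin = bins, n1_latency = lat2))
  bx <- bins - mean(bins); by <- lat2 - mean(lat2)
  slope_hat <- sum(bx * by) / sum(bx^2)
  expect_equal(tr2$slope, slope_hat, tolerance = 1e-10)
  expect_equal(tr2$r_squared, sum(bx * by)^2 / (sum(bx^2) * sum(by^2)),
               tolerance = 1e-10)
  # shuffling destroys the trend: the observed R^2 sits far in the upper
  # tail of the permutation distribution, whose bulk is near zero
  r2s <- replicate(1000, {
    latency_trend(data.frame(bin = bins,
                             n1_latency = sample(lat2)))$r_squared
  })
  expect_lt(stats::median(r2s), 0.3)
  expect_gt(mean(r2s < tr2$r_squared), 0.95)
  expect_error(latency_trend(data.frame(bin = 1:2, n1_latency = c(1, 2))),
               "at least 3")
})
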