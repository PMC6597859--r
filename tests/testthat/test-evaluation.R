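test_that("Pearson accuracy behaves as a correlation per channel", {
  set.seed(20)
  a <- matrix(stats::rnorm(600), 200, 3)
  expect_equal(pearson_accuracy(a, a), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(pearson_accuracy(-a, a), c(-1, -1, -1), ignore_attr = TRUE)
  flat <- a; flat[, 2] <- 0
  expect_true(is.na(pearson_accuracy(flat, a)[2]))
  # independent noise at large n concentrates near zero (SD ~ 1/sqrt(n))
  n <- 19200
  r <- pearson_accuracy(matrix(stats::rnorm(n)), matrix(stats::rnorm(n)))
  expect_lt(abs(r), 0.05)
})

test_that("fast Gram-statistics CV equals the literal fit/predict CV", {
  for (mode in c("repeated", "distinct")) {
    d <- tiny_dataset(n_trials = 4, seconds = 6, channels = 3, seed = 21,
                      mode = mode, bins = 4)
    rec <- stimulus_recipes(db_binning(8, 4), scale = envelope_scale(d))
    w <- lag_window(-50, 200, 128)
    grid <- c(1e-4, 1, 100)
    fast <- nested_cv(d, rec$ab, w, grid)
    slow <- nested_cv_literal(d, rec$ab, w, grid)
    expect_equal(fast$inner_accuracies, slow$inner, tolerance = 1e-8)
    expect_equal(unname(fast$test_accuracies), slow$test_accuracies,
                 tolerance = 1e-8)
    expect_equal(fast$lambda_selected, slow$lambda_selected)
    expect_equal(fast$overall, slow$overall, tolerance = 1e-8)
  }
})

test_that("nested CV partitions folds correctly", {
  d <- tiny_dataset(n_trials = 3, seconds = 5, channels = 2, seed = 22)
  rec <- stimulus_recipes(scale = envelope_scale(d))
  cv <- nested_cv(d, rec$env, lag_window(0, 100, 128), c(0.1, 10))
  # 3 outer folds, each with 2 inner validation folds
  expect_equal(nrow(cv$test_accuracies), 3)
  for (t in 1:3) {
    expect_true(all(is.na(cv$inner_accuracies[t, t, , ])))
    expect_true(all(!is.na(cv$inner_accuracies[t, -t, , ])))
  }
  expect_error(nested_cv(structure(list(trials = d$trials[1:2], fs = 128,
                                        stimulus_mode = "repeated"),
                                   class = "trf_dataset"),
                         rec$env, lag_window(0, 100, 128), 1),
               "at least 3")
})

test_that("channel selection ranks by mean accuracy with index tie-break", {
  cv <- structure(list(test_accuracies = rbind(c(0.1, 0.5, 0.3),
                                               c(0.1, 0.5, 0.3))),
                  class = "trf_cv")
  expect_equal(select_channels(cv, 3), c(2, 3, 1))
  expect_equal(sort(select_channels(cv, 2)), c(2, 3))
  tied <- structure(list(test_accuracies = rbind(c(0.4, 0.2, 0.4))),
                    class = "trf_cv")
  expect_equal(select_channels(tied, 1), 1)  # tie resolves to lower index
  expect_error(select_channels(cv, 9), "exceeds")
})

test_that("AIC penalises parameters and follows the Gaussian form", {
  set.seed(23)
  pred <- matrix(stats::rnorm(300), 100, 3)
  act <- pred + matrix(stats::rnorm(300, sd = 0.5), 100, 3)
  a10 <- aic_score(pred, act, 10)
  a13 <- aic_score(pred, act, 13)
  expect_equal(a13 - a10, rep(6, 3))       # 2 * delta-k exactly
  # halving RSS at fixed k changes AIC by n ln(1/2)
  act2 <- pred + (act - pred) / sqrt(2)
  expect_equal(aic_score(pred, act2, 10) - a10, rep(100 * log(1 / 2), 3),
               tolerance = 1e-10)
  # direct-formula oracle
  rss <- colSums((act - pred)^2)
  expect_equal(a10, 100 * log(rss / 100) + 20, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(aic_score(pred, pred, 2), rep(-Inf, 3), ignore_attr = TRUE)
})

test_that("paired comparison reproduces a hand-computed t, d and fallback", {
  a <- c(0.30, 0.28, 0.35, 0.31, 0.29, 0.33, 0.27, 0.36, 0.32, 0.30)
  b <- a - c(0.02, 0.01, 0.03, 0.02, 0.00, 0.02, 0.01, 0.04, 0.02, 0.01)
  cmp <- paired_comparison(a, b)
  dif <- a - b
  t_hand <- mean(dif) / (stats::sd(dif) / sqrt(10))
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$d, t_hand / sqrt(10), tolerance = 1e-12)
  expect_equal(cmp$n, 10)
  expect_lt(cmp$p, 0.05)
  expect_true(is.finite(cmp$wilcoxon_p))
  expect_true(!is.na(cmp$normal_a))
  deg <- paired_comparison(a, a)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t))
  expect_error(paired_comparison(a, a[1:3]), "equal length")
})

test_that("paired effect size is t over root n", {
  expect_equal(cohens_d(0, 25), 0)
  expect_equal(cohens_d(sqrt(13), 13), 1)
  expect_equal(cohens_d(-2, 4), -1)
})
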