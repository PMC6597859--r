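test_that("SPL transform maps amplitudes to dB with floor clipping", {
  e <- envelope(c(1, 0.1, 0, 0.5), 128)
  s <- spl_envelope(e, floor_db = -80)
  expect_equal(as.numeric(s)[1:3], c(0, -20, -80))
  expect_equal(as.numeric(s)[4], 20 * log10(0.5))
  expect_error(spl_envelope(e, floor_db = 10), "negative")
})

test_that("onset/offset envelopes rectify the first difference", {
  e <- envelope(c(0, 1, 0.5, 0.7), 128)
  expect_equal(as.numeric(onset_envelope(e)), c(0, 1, 0, 0.2))
  expect_equal(as.numeric(offset_envelope(e)), c(0, 0, 0.5, 0))
  const <- envelope(rep(2, 10), 128)
  expect_equal(as.numeric(onset_envelope(const)), rep(0, 10))
  expect_equal(as.numeric(offset_envelope(const)), rep(0, 10))
  inc <- envelope(cumsum(runif(20)), 128)
  expect_equal(as.numeric(onset_envelope(inc)), c(0, diff(as.numeric(inc))))
})

test_that("onset minus offset reconstructs the derivative for any envelope", {
  set.seed(2)
  for (i in 1:5) {
    e <- envelope(abs(stats::rnorm(50)), 64)
    expect_equal(as.numeric(onset_envelope(e)) - as.numeric(offset_envelope(e)),
                 c(0, diff(as.numeric(e))))
    expect_equal(as.numeric(derivative_envelope(e)), c(0, diff(as.numeric(e))))
  }
})

test_that("logarithmic bin edges follow the 10^(k w / 20) rule", {
  b <- db_binning(8, 8)
  raw <- c(0, 10^(8 * (1:8) / 20))
  expect_equal(b$edges, raw / raw[9])
  # interior edge k = 7 of an 8 x 8 dB scheme is 10^(-8/20)
  expect_equal(b$edges[8], 10^(-8 / 20), tolerance = 1e-12)
  expect_equal(db_binning(20, 2)$edges, c(0, 0.1, 1))
  # strictly increasing, anchored at 0 and 1
  expect_true(all(diff(b$edges) > 0))
  expect_identical(b$edges[c(1, 9)], c(0, 1))
})

test_that("bin edges are invariant to overall amplitude scale", {
  # normalising by the top edge removes any common factor, so schemes with
  # the same width/count agree regardless of how raw edges would be scaled
  b1 <- db_binning(8, 8)
  raw <- c(0, 10^(8 * (1:8) / 20)) * 123.4
  expect_equal(b1$edges, raw / raw[9])
})

test_that("amplitude binning applies the affine within-bin map", {
  b <- db_binning(20, 2)  # edges 0, 0.1, 1
  e <- envelope(c(0.05, 0.55, 1.0), 128)
  r <- ab_envelope(e, b, scale = 1)
  expect_equal(unclass(r)[1, ], c(bin1 = 0.5, bin2 = 0))
  expect_equal(unclass(r)[2, ], c(bin1 = 0, bin2 = 0.5))
  expect_equal(unclass(r)[3, ], c(bin1 = 0, bin2 = 1))
  expect_error(ab_envelope(envelope(rep(0, 10), 128), b), "dynamic range")
})

test_that("binning is a partition and a lossless coding of the envelope", {
  set.seed(3)
  for (B in c(2, 5, 8)) {
    b <- db_binning(8, B)
    v <- stats::runif(500)
    e <- envelope(v, 128)
    r <- ab_envelope(e, b)
    expect_true(all(r >= 0 & r <= 1))
    nz <- rowSums(unclass(r) != 0)
    expect_true(all(nz <= 1))
    # bin-membership counts summed over bins account for every sample
    memb <- findInterval(v / max(v), b$edges, rightmost.closed = TRUE)
    expect_equal(sum(tabulate(memb, B)), 500)
    rec <- ab_invert(r, b)
    expect_equal(as.numeric(rec), v / max(v), tolerance = 1e-12)
  }
})

test_that("representation concatenation stacks features", {
  set.seed(4)
  e <- envelope(stats::runif(300), 128)
  ab <- ab_envelope(e, db_binning(8, 8))
  ons <- as_stim_rep(onset_envelope(e), "onset")
  both <- concat_reps(ab, ons)
  expect_equal(ncol(both), 9)
  expect_identical(colnames(both), c(paste0("bin", 1:8), "onset"))
  expect_equal(unclass(concat_reps(ab)), unclass(ab))
  ab_ons <- ab_envelope(onset_envelope(e), db_binning(8, 8))
  expect_equal(ncol(concat_reps(ab, ab_ons)), 16)
  short <- stim_rep(matrix(1, 10, 1), 128)
  expect_error(concat_reps(ab, short), "share length")
  wrong_fs <- stim_rep(matrix(1, 300, 1), 64)
  expect_error(concat_reps(ab, wrong_fs), "share length|sampling")
})
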