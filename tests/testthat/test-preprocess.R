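# Prefilter contract, rate conversion, exam exclusion, round selection,
# windowing and normalization.

test_that("band-pass half-power points sit at 0.5 and 15 Hz", {
  b <- design_bandpass(64)
  # independent response measurement on a dense grid
  H <- function(f) {
    k <- seq_along(b) - 1
    abs(sapply(f, function(fi) sum(b * exp(-2i * pi * fi * k / 64))))
  }
  ref <- max(H(seq(1, 10, by = 0.25)))
  hp_hi <- uniroot(function(f) H(f) - ref / sqrt(2), c(10, 20), tol = 1e-5)$root
  hp_lo <- uniroot(function(f) H(f) - ref / sqrt(2), c(0.1, 2), tol = 1e-5)$root
  expect_lt(abs(hp_hi - 15), 0.1)
  expect_lt(abs(hp_lo - 0.5), 0.1)
})

test_that("DC is rejected and the 5 Hz passband is preserved", {
  n <- 5120
  ydc <- bandpass_filter(rep(1, n), 64)
  expect_lt(max(abs(ydc[1000:4000])), 0.01)
  x <- sin(2 * pi * 5 * (0:(n - 1)) / 64)
  y <- bandpass_filter(x, 64)
  expect_lt(abs(sd(y[1000:4000]) / sd(x[1000:4000]) - 1), 0.05)
})

test_that("the filter is nearly idempotent on an already band-limited signal", {
  set.seed(1)
  n <- 8000
  x <- bandpass_filter(rnorm(n), 64, lo = 1, hi = 10)
  core <- 2000:6000
  y <- bandpass_filter(x, 64)
  expect_lt(sd(y[core] - x[core]) / sd(x[core]), 0.01)
})

test_that("filtering a too-short signal names the minimum length", {
  expect_error(bandpass_filter(rnorm(100), 64), "513")
})

test_that("resampling to 64 Hz has the documented length and spectrum", {
  x <- sin(2 * pi * 5 * (0:5999) / 100)
  y <- resample_to_64(x, 100)
  expect_identical(length(y), 3840L)
  p <- periodogram_os(y[500:3500], 64)
  expect_lt(abs(p$freq[which.max(p$power)] - 5), 0.1)
  expect_identical(resample_to_64(x, 64), x)
  expect_error(resample_to_64(x, 50), "upsampl|>= 64")
})

test_that("exam exclusion splits recordings and never concatenates across gaps", {
  X <- matrix(rnorm(300 * 64 * 6), ncol = 6)
  segs <- exclude_exam_segments(X, 64, NULL)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$X[[1]], X)

  iv <- matrix(c(120, 180), 1)
  segs <- exclude_exam_segments(X, 64, iv)
  expect_identical(nrow(segs), 2L)
  total_s <- sum(vapply(segs$X, nrow, integer(1))) / 64
  expect_equal(total_s, 240)
  expect_equal(segs$t_start, c(0, 180))

  expect_warning(out <- exclude_exam_segments(X, 64, matrix(c(0, 300), 1)),
                 "whole recording")
  expect_identical(nrow(out), 0L)
  expect_error(exclude_exam_segments(X, 64, matrix(c(0, 60, 30, 90), 2,
                                                   byrow = TRUE)), "overlap")
})

test_that("round selection caps at 10 min and anchors at assessments", {
  fs <- 64
  seg25 <- tibble::tibble(t_start = 0,
                          X = list(matrix(rnorm(25 * 60 * fs * 6), ncol = 6)))
  r <- select_rounds(seg25, data.frame(time = 0, total = 30), fs)
  expect_identical(nrow(r), 1L)
  expect_equal(r$duration_s, 600)

  seg4 <- tibble::tibble(t_start = 0,
                         X = list(matrix(rnorm(4 * 60 * fs * 6), ncol = 6)))
  r <- select_rounds(seg4, data.frame(time = 0, total = 20), fs)
  expect_equal(r$duration_s, 240)

  # 2-h continuous recording, two assessments -> two capped rounds
  seg2h <- tibble::tibble(t_start = 0,
                          X = list(matrix(rnorm(7200 * fs * 3) , ncol = 3)))
  r <- select_rounds(seg2h, data.frame(time = c(0, 7000), total = c(35, 18)), fs)
  expect_identical(nrow(r), 2L)
  expect_true(all(r$duration_s <= 600))
  expect_equal(r$updrs_total, c(35, 18))
  expect_lte(abs(r$t_start[2] + r$duration_s[2] - 7000), 600)

  short <- tibble::tibble(t_start = 0, X = list(matrix(rnorm(30 * fs), ncol = 1)))
  expect_warning(out <- select_rounds(short, data.frame(time = 0, total = 5), fs),
                 "no segment")
  expect_identical(nrow(out), 0L)
})

test_that("windowing yields 12 short windows per long window and drops remainders", {
  mk <- function(sec) matrix(rnorm(sec * 64 * 6), ncol = 6)
  w1 <- segment_windows(mk(60), 64)
  expect_identical(c(w1$n_long, w1$n_short), c(1L, 12L))
  w4 <- segment_windows(mk(240), 64)
  expect_identical(c(w4$n_long, w4$n_short), c(4L, 48L))
  w65 <- segment_windows(mk(65), 64)
  expect_identical(c(w65$n_long, w65$n_short), c(1L, 12L))
  expect_error(segment_windows(mk(59), 64), "one minute")
  # conservation across random durations
  for (sec in c(61, 119, 187)) {
    w <- segment_windows(mk(sec), 64)
    expect_identical(w$n_short, 12L * w$n_long)
    expect_identical(nrow(w$short[[1]]), 320L)
    expect_identical(nrow(w$long[[1]]), 3840L)
  }
})

test_that("z-scoring uses training statistics only and handles degenerate columns", {
  set.seed(3)
  train <- cbind(rnorm(100, 5, 2), rnorm(100, -1, 0.1), rep(7, 100))
  st <- norm_stats(train)
  z <- normalize(train, st)
  expect_true(all(abs(colMeans(z)) < 1e-6))
  expect_true(all(abs(apply(z[, 1:2], 2, sd) - 1) < 1e-6))
  expect_true(all(z[, 3] == 0))                 # zero-variance convention

  test <- cbind(rnorm(50, 9, 2), rnorm(50, 0, 0.1), rep(7, 50))
  zt <- normalize(test, st)
  expect_gt(abs(mean(zt[, 1])), 0.5)            # train stats != test stats
  expect_error(normalize(test[, 1:2], st), "dimensions")
})

test_that("a 100 Hz activity corpus is brought to 64 Hz before features", {
  corp <- synth_activity_corpus(n_subjects = 2, n_rounds = 12, fs = 100,
                                seed = 21)
  expect_identical(nrow(corp$X[[1]]), 6000L)
  feats <- activity_features(corp[1:2, ])
  expect_identical(dim(feats$S[[1]]), c(12L, 26L))   # 12 windows of 64 Hz data
})
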