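# Feature-operator oracles: closed forms, brute-force equivalence, and the
# structural contracts of the 26/32-dimensional feature vectors.

fs <- 64
t5 <- (0:319) / fs

test_that("band power matches the sinusoid closed form and leaks little", {
  x <- sin(2 * pi * 5 * t5)
  expect_lt(abs(band_power(x, 4, 6, fs) - 0.5) / 0.5, 0.02)
  expect_lt(band_power(x, 8, 10, fs), 0.005)
  expect_identical(band_power(numeric(320) , 4, 6, fs), 0)
  expect_error(band_power(numeric(0), 4, 6, fs), "empty")
  expect_error(band_power(x, 6, 4, fs), "f_lo")
  # Parseval: full-band power equals the time-domain mean square
  set.seed(1); z <- rnorm(320)
  p <- periodogram_os(z, fs)
  expect_equal(sum(p$power), mean(z^2), tolerance = 1e-10)
})

test_that("percentage power above 4 Hz separates tremor-band from low-band tones", {
  expect_lt(abs(percent_power_above(sin(2 * pi * 5 * t5), 4, fs) - 100), 2)
  expect_lt(percent_power_above(sin(2 * pi * 2 * t5), 4, fs), 2)
  expect_identical(percent_power_above(numeric(320), 4, fs), 0)
})

test_that("autocorrelation peaks recover the oscillation period", {
  x <- sin(2 * pi * 4 * t5)
  st <- autocorr_peak_stats(x, fs)
  expect_lt(abs(st["first_peak_lag_s"] - fs / 4 / fs), 1 / fs + 1e-12)
  expect_gt(st["first_peak_amp"], 0.9)
  expect_identical(unname(autocorr_peak_stats(numeric(320), fs)),
                   c(0, 0, 0, 0))
  expect_identical(unname(autocorr_peak_stats(rep(2, 320), fs)),
                   c(0, 0, 0, 0))
})

test_that("fft autocorrelation equals the direct-sum oracle", {
  set.seed(4)
  for (n in c(120, 300)) {
    x <- rnorm(n)
    ours <- updrsens:::.autocorr(x)
    ref <- oracle_autocorr(x, n - 1)
    expect_lt(max(abs(ours - ref)), 1e-9)
  }
})

test_that("spectral entropy is low for tones and high for white noise", {
  expect_lt(spectral_entropy(sin(2 * pi * 5 * t5), fs), 0.2)
  set.seed(5)
  hs <- replicate(100, spectral_entropy(rnorm(320), fs))
  expect_gt(mean(hs), 0.9)
  expect_identical(spectral_entropy(numeric(320), fs), 0)
})

test_that("dominant and secondary frequencies resolve a two-tone mixture", {
  x <- 2 * sin(2 * pi * 3 * t5) + sin(2 * pi * 7 * t5)
  ds <- dominant_secondary_freqs(x, fs)
  expect_equal(unname(ds["f1"]), 3, tolerance = 0.21)
  expect_equal(unname(ds["f2"]), 7, tolerance = 0.21)
  expect_gt(ds["p1"], ds["p2"])
  single <- dominant_secondary_freqs(sin(2 * pi * 5 * t5), fs)
  expect_equal(unname(single["f1"]), 5, tolerance = 0.21)
  expect_identical(unname(single[c("f2", "p2")]), c(0, 0))
  expect_identical(unname(dominant_secondary_freqs(numeric(320), fs)),
                   c(0, 0, 0, 0))
})

test_that("zero-lag cross-correlation follows the Pearson conventions", {
  set.seed(6)
  x <- rnorm(320)
  expect_equal(axis_crosscorr(x, x), 1)
  expect_equal(axis_crosscorr(x, -x), -1)
  expect_identical(axis_crosscorr(x, rep(1, 320)), 0)
  expect_error(axis_crosscorr(x, rnorm(100)), "equal length")
  rs <- replicate(100, abs(axis_crosscorr(rnorm(320), rnorm(320))))
  expect_lt(quantile(rs, 0.95), 0.2)
})

test_that("mean absolute jerk matches the sinusoid closed form", {
  expect_identical(mean_abs_jerk(rep(3, 320), fs), 0)
  expect_lt(mean_abs_jerk(seq(0, 1, length.out = 320), fs), 1e-9)
  A <- 1.5; f0 <- 5
  x <- A * sin(2 * pi * f0 * t5)
  expect_lt(abs(mean_abs_jerk(x, fs) - A * (2 * pi * f0)^2 * 2 / pi) /
              (A * (2 * pi * f0)^2 * 2 / pi), 0.03)
})

test_that("peak-to-peak and histogram entropy behave on analytic signals", {
  expect_lt(abs(peak_to_peak(2 * sin(2 * pi * 5 * t5)) - 4) / 4, 0.01)
  expect_identical(peak_to_peak(rep(1, 10)), 0)
  expect_identical(peak_to_peak(3.2), 0)

  expect_identical(shannon_entropy(rep(5, 100)), 0)
  set.seed(7)
  hs <- replicate(100, shannon_entropy(runif(3840, -1, 1)))
  expect_lt(abs(mean(hs) - log(16)) / log(16), 0.05)
  expect_lt(abs(shannon_entropy(rep(c(-1, 1), 100)) - log(2)) / log(2), 0.05)
})

test_that("sample entropy equals the brute-force double-loop oracle", {
  expect_identical(sample_entropy(rep(1, 200)), 0)
  set.seed(8)
  for (rep in 1:5) {
    x <- rnorm(200)
    expect_lt(abs(sample_entropy(x) - oracle_sampen(x)), 1e-9)
  }
  # regularity ordering: periodic sine below white noise of equal sd
  for (seed in 1:20) {
    set.seed(seed)
    s <- sin(2 * pi * 5 * (0:499) / fs)
    n <- rnorm(500, sd = sd(s))
    expect_lte(sample_entropy(s), sample_entropy(n))
  }
})

test_that("gini index matches direct formula evaluation", {
  expect_identical(gini_index(rep(2, 8)), 0)
  expect_identical(gini_index(c(0, 0, 0, 1)), 0.75)
  expect_identical(gini_index(numeric(5)), 0)
  set.seed(9)
  x <- rnorm(50)
  a <- sort(abs(x)); n <- 50
  expect_equal(gini_index(x), sum((2 * 1:n - n - 1) * a) / (n * sum(a)))
})

test_that("population moments match Monte-Carlo and closed-form cases", {
  set.seed(10)
  ms <- t(replicate(50, moment_stats(rnorm(3840))))
  expect_lt(abs(mean(ms[, "mean"])), 0.1)
  expect_lt(abs(mean(ms[, "sd"]) - 1), 0.1)
  expect_lt(abs(mean(ms[, "skewness"])), 0.1)
  expect_lt(abs(mean(ms[, "excess_kurtosis"])), 0.1)
  expect_identical(unname(moment_stats(rep(4.5, 10))), c(4.5, 0, 0, 0))
  expect_equal(unname(moment_stats(rep(c(-1, 1), 50))["excess_kurtosis"]), -2)
})

test_that("short and long feature vectors have the contracted dimensions", {
  set.seed(11)
  W <- matrix(rnorm(320 * 6), ncol = 6)
  sf <- extract_short_features(W, fs)
  expect_length(sf, 26L)
  expect_true(all(is.finite(sf)))
  WL <- matrix(rnorm(3840 * 6), ncol = 6)
  lf <- extract_long_features(WL, fs)
  expect_length(lf, 32L)
  expect_true(all(is.finite(lf)))
  expect_error(extract_short_features(W[, 1:5], fs), "6")
  expect_error(extract_long_features(WL[1:100, ], fs), "3840")
  # zero windows collapse to the zero conventions
  z <- extract_short_features(matrix(0, 320, 6), fs)
  expect_true(all(z == 0))
})

test_that("axis permutation within a sensor leaves the feature vector unchanged", {
  set.seed(12)
  W <- matrix(rnorm(320 * 6), ncol = 6)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    Wp <- W[, c(perm, 3 + perm)]
    expect_equal(extract_short_features(Wp, fs), extract_short_features(W, fs),
                 tolerance = 1e-12)
  }
})

test_that("the wrist tremor-band feature rises monotonically with tremor burden", {
  prof <- symptom_profile()
  bp <- vapply(c(0L, 1L, 2L, 3L, 4L), function(lv) {
    items <- rep(0L, 27); items[1:7] <- lv
    r <- synth_round(updrs_label(items), prof, 60, 64, seed = 77)
    X <- bandpass_filter(r$X, 64)
    mean(extract_round_features(X, 64)$S[, "wrist_bp_4_6"])
  }, numeric(1))
  expect_true(all(diff(bp) > 0))
})
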