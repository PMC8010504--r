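# Spectrogram tensor: shapes, tone localisation, shift covariance and
# amplitude linearity.

test_that("a full 1-min window yields a 111 x 81 x 6 magnitude tensor", {
  set.seed(1)
  W <- matrix(rnorm(3840 * 6), ncol = 6)
  spg <- compute_spectrogram(W, 64)
  expect_identical(dim(spg), c(111L, 81L, 6L))
  expect_true(all(spg >= 0))
  expect_equal(attr(spg, "hop_s"), 0.5)
  expect_equal(max(attr(spg, "freq")), 16)
  expect_error(compute_spectrogram(W[1:100, ], 64), "3840")
  expect_true(all(compute_spectrogram(matrix(0, 3840, 6), 64) == 0))
})

test_that("a pure tone peaks at its frequency bin in every frame", {
  tone <- matrix(rep(sin(2 * pi * 5 * (0:3839) / 64), 6), ncol = 6)
  spg <- compute_spectrogram(tone, 64)
  bins <- apply(spg[, , 3], 1, which.max)
  expect_true(all(attr(spg, "freq")[bins] == 5))
})

test_that("shifting the input by one hop shifts the frames by one", {
  set.seed(2)
  x <- rnorm(3840 + 32)
  W1 <- matrix(rep(x[1:3840], 6), ncol = 6)
  W2 <- matrix(rep(x[33:(3840 + 32)], 6), ncol = 6)
  s1 <- compute_spectrogram(W1, 64)
  s2 <- compute_spectrogram(W2, 64)
  expect_lt(max(abs(s1[2:111, , 1] - s2[1:110, , 1])), 1e-6)
})

test_that("doubling the amplitude doubles every magnitude", {
  set.seed(3)
  W <- matrix(rnorm(3840 * 6), ncol = 6)
  s1 <- compute_spectrogram(W, 64)
  s2 <- compute_spectrogram(2 * W, 64)
  expect_equal(as.numeric(s2), as.numeric(2 * s1), tolerance = 1e-12)
})
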