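# Model forward contracts: LSTM equation fidelity, CNN shapes, ensemble
# bounds, and the tree-boosting baseline.

test_that("the LSTM forward pass matches a step-by-step scalar oracle", {
  set.seed(21)
  for (rep in 1:3) {
    stack <- updrsens:::lstm_stack_init(3L, 4L, 2L)
    head <- updrsens:::dense_init(4L, 1L)
    Fv <- matrix(rnorm(9), 3, 3)
    ours <- updrsens:::dense_fwd(
      matrix(updrsens:::lstm_stack_fwd(Fv, stack)$h_last, 1), head)[1, 1]
    ref <- oracle_lstm_forward(Fv, stack, head)
    expect_lt(abs(ours - ref), 1e-6)
  }
})

test_that("zero weights propagate to a zero hidden state", {
  stack <- updrsens:::lstm_stack_init(5L, 8L, 1L)
  stack <- updrsens:::map_params(function(x) x * 0, stack)
  out <- updrsens:::lstm_stack_fwd(matrix(rnorm(50), 10, 5), stack)
  expect_true(all(out$h_last == 0))
})

test_that("repeated identical input drives the hidden state to a fixed point", {
  set.seed(22)
  stack <- updrsens:::lstm_stack_init(4L, 6L, 1L)
  Fv <- matrix(rep(rnorm(4), each = 60), 60, 4)
  H <- updrsens:::lstm_stack_fwd(Fv, stack)$H
  steps <- sqrt(rowSums(diff(H)^2))
  expect_lt(steps[59], steps[10])
  expect_lt(steps[59], 1e-4)
})

test_that("dual-channel forward enforces alignment and the zero-weight case", {
  spec <- model_spec("dual_lstm", lstm_layers = 1, n_h = 16)
  set.seed(23)
  p <- updrsens:::dual_lstm_init(spec)
  S <- matrix(rnorm(24 * 26), 24, 26)
  L <- matrix(rnorm(2 * 32), 2, 32)
  y <- dual_channel_forward(S, L, p)
  expect_length(y, 1L)
  expect_true(is.finite(y))
  expect_error(dual_channel_forward(S[1:23, ], L, p), "mismatch")

  p0 <- updrsens:::map_params(function(x) x * 0, p)
  p0$head$b <- 7.5
  expect_equal(dual_channel_forward(S, L, p0), 7.5)
})

test_that("the 1D CNN embedding is 96-dim regardless of Block-2 depth", {
  set.seed(24)
  c1 <- build_cnn1d(model_spec("cnn1d_lstm", conv_block2_repeats = 1))
  c2 <- build_cnn1d(model_spec("cnn1d_lstm", conv_block2_repeats = 2))
  X <- matrix(rnorm(320 * 6), ncol = 6)
  e1 <- updrsens:::cnn_embed(c1, c1$params, list(X))
  e2 <- updrsens:::cnn_embed(c2, c2$params, list(X))
  expect_identical(ncol(e1), 96L)
  expect_identical(ncol(e2), 96L)
  expect_gt(updrsens:::conv_n_params(c2$params),
            updrsens:::conv_n_params(c1$params))
  # zero input with zero-bias network gives a zero embedding
  ez <- updrsens:::cnn_embed(c1, c1$params, list(matrix(0, 320, 6)))
  expect_true(all(ez == 0))
})

test_that("CNN-LSTM forward handles single-window rounds and padding masks", {
  set.seed(25)
  spec <- model_spec("cnn1d_lstm", lstm_layers = 1, n_h = 16)
  cnn <- build_cnn1d(spec)
  model <- list(cnn = cnn,
                params = updrsens:::cnn_lstm_init(cnn, spec))
  w1 <- list(matrix(rnorm(320 * 6), ncol = 6))
  expect_true(is.finite(cnn_lstm_forward(model, w1)))
  expect_error(cnn_lstm_forward(model, list()), "no windows")

  wins <- replicate(3, matrix(rnorm(320 * 6), ncol = 6), simplify = FALSE)
  expect_lt(abs(cnn_lstm_forward(model, wins) -
                cnn_lstm_forward(model, wins, pad_to = 7)), 1e-5)

  pz <- updrsens:::map_params(function(x) x * 0, model$params)
  pz$fc2$b <- 3.25
  expect_equal(updrsens:::cnn_head_fwd(
    updrsens:::cnn_embed(cnn, pz$cnn, wins), pz)$y, 3.25)
})

test_that("conv gradients agree with finite differences on a tiny program", {
  set.seed(26)
  prog <- list(list(op = "conv", k = 3, cin = 2, cout = 3),
               list(op = "relu"), list(op = "pool", p = 2),
               list(op = "gap"))
  pars <- updrsens:::conv_net_init(prog, 1L)
  X <- matrix(rnorm(2 * 8 * 2), 16, 2)
  loss <- function(p) {
    o <- updrsens:::conv_net_fwd(prog, p, X, 2, 8L)
    0.5 * sum(o$Y^2)
  }
  o <- updrsens:::conv_net_fwd(prog, pars, X, 2, 8L)
  g <- updrsens:::conv_net_bwd(prog, pars, o$caches, o$Y)
  eps <- 1e-6
  for (k in sample(length(pars[[1]]$W), 6)) {
    p2 <- pars
    p2[[1]]$W[k] <- p2[[1]]$W[k] + eps; lp <- loss(p2)
    p2[[1]]$W[k] <- p2[[1]]$W[k] - 2 * eps; lm <- loss(p2)
    expect_lt(abs(g[[1]]$W[k] - (lp - lm) / (2 * eps)), 1e-6)
  }
})

test_that("ensemble averaging is the mean and stays within member bounds", {
  expect_identical(ensemble_average(c(10, 20, 30)), 20)
  expect_identical(ensemble_average(c(4.2, 4.2, 4.2)), 4.2)
  expect_error(ensemble_average(c(1, 2)), "3 member")
  expect_error(ensemble_average(c(1, 2, NA)), "3 member")
  set.seed(27)
  for (rep in 1:200) {
    p <- rnorm(3, sd = 30)
    e <- ensemble_average(p)
    expect_gte(e, min(p)); expect_lte(e, max(p))
  }
})

test_that("tree-boosting windows are 58-dimensional and recover linear signal", {
  set.seed(28)
  S <- matrix(rnorm(24 * 26), 24, 26)
  L <- matrix(rnorm(2 * 32), 2, 32)
  SL <- gtb_windows(S, L)
  expect_identical(dim(SL), c(24L, 58L))
  expect_identical(SL[13, 27:58], L[2, ])
  expect_error(gtb_windows(S[1:20, ], L), "12")
  expect_error(gtb_fit_predict(list(), list(), grid = gtb_grid(trees = c())),
               "empty")

  mk <- function(n, y) {
    list(S = lapply(seq_len(n), function(i) {
      m <- matrix(rnorm(12 * 26), 12, 26); m[, 1] <- y[i] + rnorm(12, sd = 2); m
    }),
    L = lapply(seq_len(n), function(i) matrix(rnorm(32), 1, 32)),
    y = y)
  }
  ytr <- runif(40, 0, 60); yte <- runif(15, 0, 60)
  tr <- mk(40, ytr); te <- mk(15, yte)
  pred <- gtb_fit_predict(tr, te, grid = gtb_grid(trees = 110, depth = 3,
                                                  colsample = 0.5))
  expect_gte(cor(yte, pred), 0.9)

  # constant-label training collapses to that constant
  trc <- mk(10, rep(12, 10))
  pc <- gtb_fit_predict(trc, mk(4, runif(4)), grid = gtb_grid(trees = 50,
                                                              depth = 3,
                                                              colsample = 0.5))
  expect_true(all(abs(pc - 12) < 1e-4))
})
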