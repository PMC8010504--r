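# CNN-LSTM regressors: a convolutional feature extractor per window, a
# many-to-one LSTM over the window sequence, and a two-layer fully
# connected head (fc_width nodes, then one output node).

#' Model hyperparameter specification
#'
#' Validated hyperparameters for the regression models, kept within the
#' searched ranges (LSTM layers 1--3, hidden states 16--224, Conv Block-2
#' repeats 1--4, dropout 0.5).
#'
#' @param kind One of `"dual_lstm"`, `"cnn1d_lstm"`, `"cnn2d_lstm"`, `"gtb"`.
#' @param lstm_layers Number of stacked LSTM layers (1--3).
#' @param n_h Hidden-state width (16--224).
#' @param conv_block2_repeats Conv Block-2 repetitions (1--4).
#' @param dropout Dropout rate on embeddings before the LSTM.
#' @param fc_width Width of the first fully connected head layer.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("dual_lstm", "cnn1d_lstm", "cnn2d_lstm", "gtb"),
                       lstm_layers = 2L, n_h = 64L, conv_block2_repeats = 1L,
                       dropout = 0.5, fc_width = 96L) {
  kind <- match.arg(kind)
  if (!lstm_layers %in% 1:3) stop("lstm_layers must be 1..3")
  if (n_h < 16 || n_h > 224) stop("n_h must be in 16..224")
  if (!conv_block2_repeats %in% 1:4) stop("conv_block2_repeats must be 1..4")
  structure(list(kind = kind, lstm_layers = as.integer(lstm_layers),
                 n_h = as.integer(n_h),
                 conv_block2_repeats = as.integer(conv_block2_repeats),
                 dropout = dropout, fc_width = as.integer(fc_width)),
            class = "model_spec")
}

# Three-block convolutional program.  Block-1: two convs (32 filters),
# max-pool; Block-2 (repeated): two convs (64 filters), max-pool; Block-3:
# one conv layer of fc_width filters + global average pooling, so the
# embedding width matches the fully connected head.  Every conv is followed
# by ReLU, stride 1, same padding.  The 2D variant starts with a 2x2
# average pooling of the spectrogram to halve the (oversampled)
# time-frequency resolution.
.cnn_program <- function(k, repeats, embed, pool, prepool = NULL) {
  prog <- list()
  if (!is.null(prepool)) prog <- c(prog, list(list(op = "avgpool", p = prepool)))
  prog <- c(prog,
            list(list(op = "conv", k = k, cin = 6L, cout = 32L),
                 list(op = "relu"),
                 list(op = "conv", k = k, cin = 32L, cout = 32L),
                 list(op = "relu"),
                 list(op = "pool", p = pool)))
  cin <- 32L
  for (r in seq_len(repeats)) {
    prog <- c(prog,
              list(list(op = "conv", k = k, cin = cin, cout = 64L),
                   list(op = "relu"),
                   list(op = "conv", k = k, cin = 64L, cout = 64L),
                   list(op = "relu"),
                   list(op = "pool", p = pool)))
    cin <- 64L
  }
  c(prog, list(list(op = "conv", k = k, cin = cin, cout = embed),
               list(op = "relu"),
               list(op = "gap")))
}

#' Build the 1D CNN feature extractor
#'
#' Two 32-filter width-8 convolutions with max-pooling (Block-1), 1--4
#' repeats of the 64-filter Block-2, and a Block-3 bottleneck conv +
#' global average pooling producing a `fc_width`-dimensional embedding per
#' 5-s raw window.
#'
#' @param spec A [model_spec()] of kind `"cnn1d_lstm"`.
#' @return A list with `program`, randomly initialised `params`, `ndim = 1`,
#'   `dims` (window length) and `embed_dim`.
#' @export
build_cnn1d <- function(spec = model_spec("cnn1d_lstm")) {
  program <- .cnn_program(8L, spec$conv_block2_repeats, spec$fc_width,
                          pool = 4L)
  list(program = program, params = conv_net_init(program, 1L), ndim = 1L,
       dims = 320L, embed_dim = spec$fc_width)
}

#' Build the 2D CNN feature extractor for spectrogram tensors
#'
#' Same block structure as [build_cnn1d()] with 5 x 5 filters on the
#' frames x frequency x axes tensor; a 2 x 2 average pooling first reduces
#' the oversampled time-frequency grid.
#'
#' @param spec A [model_spec()] of kind `"cnn2d_lstm"`.
#' @param dims Tensor frame/bin counts, default `c(111, 81)`.
#' @return As [build_cnn1d()] with `ndim = 2`.
#' @export
build_cnn2d <- function(spec = model_spec("cnn2d_lstm"), dims = c(111L, 81L)) {
  program <- .cnn_program(5L, spec$conv_block2_repeats, spec$fc_width,
                          pool = 4L, prepool = 2L)
  list(program = program, params = conv_net_init(program, 2L), ndim = 2L,
       dims = dims, embed_dim = spec$fc_width)
}

# Count of trainable parameters in a conv program.
conv_n_params <- function(params) {
  sum(vapply(params, function(p) {
    if (is.null(p)) 0L else length(p$W) + length(p$b)
  }, integer(1)))
}

# Full CNN-LSTM model parameters.
cnn_lstm_init <- function(cnn, spec) {
  list(cnn = cnn$params,
       lstm = lstm_stack_init(cnn$embed_dim, spec$n_h, spec$lstm_layers),
       fc1 = dense_init(spec$n_h, spec$fc_width),
       fc2 = dense_init(spec$fc_width, 1L))
}

# Stack a round's windows into the (B * N) x 6 rows layout.
# wins: list of equal-size matrices (1D) or H x W x 6 arrays (2D).
stack_windows <- function(wins) {
  do.call(rbind, lapply(wins, function(w) {
    if (length(dim(w)) == 3L) matrix(w, prod(dim(w)[1:2]), dim(w)[3]) else w
  }))
}

# Sequence part (dropout -> LSTM -> FC(fc_width) -> ReLU -> FC(1)) on an
# embedding sequence E (n_win x embed_dim).  `upto` reads the hidden state
# at that step (masking for repetition-padded sequences).
cnn_head_fwd <- function(E, params, dropout = 0, train = FALSE, upto = NULL) {
  dp <- dropout_fwd(E, dropout, train)
  lo <- lstm_stack_fwd(dp$Y, params$lstm)
  h <- if (is.null(upto)) lo$h_last else lo$H[upto, ]
  z1 <- dense_fwd(matrix(h, 1), params$fc1)
  a1 <- relu_fwd(z1)
  y <- dense_fwd(a1, params$fc2)[1, 1]
  list(y = y, cache = list(dp = dp, lo = lo, h = h, z1 = z1, a1 = a1))
}

cnn_head_bwd <- function(cache, params, dy) {
  b2 <- dense_bwd(cache$a1, matrix(dy, 1), params$fc2)
  dz1 <- relu_bwd(cache$z1, b2$dX)
  b1 <- dense_bwd(matrix(cache$h, 1), dz1, params$fc1)
  bl <- lstm_stack_bwd(cache$lo$cache, params$lstm, as.numeric(b1$dX))
  dE <- dropout_bwd(bl$dFv, cache$dp$mask)
  list(dE = dE,
       grads = list(lstm = bl$grads, fc1 = b1$grads, fc2 = b2$grads))
}

#' CNN-LSTM forward pass for one round
#'
#' Computes per-window embeddings with the convolutional extractor (raw
#' 5-s windows for the 1D model; spectrogram tensors per 1-min window for
#' the 2D model), runs the many-to-one LSTM over the embedding sequence and
#' the two fully connected head layers, and returns one scalar UPDRS-III
#' estimate.
#'
#' @param model A fitted or initialised model list with `cnn` (from
#'   [build_cnn1d()]/[build_cnn2d()], with trained `params`) and `params`
#'   (from `cnn_lstm_init`).
#' @param wins List of the round's windows (matrices or tensors).
#' @param pad_to Optional length: the window sequence is repeated to this
#'   length (mini-batch repetition padding) and the hidden state is read at
#'   the true sequence end, so the output is padding-invariant.
#' @return Scalar estimate.
#' @export
cnn_lstm_forward <- function(model, wins, pad_to = NULL) {
  if (length(wins) == 0L) stop("round has no windows")
  n_true <- length(wins)
  if (!is.null(pad_to) && pad_to > n_true) {
    wins <- wins[((seq_len(pad_to) - 1L) %% n_true) + 1L]
  }
  X <- stack_windows(wins)
  emb <- conv_net_fwd(model$cnn$program, model$params$cnn, X,
                      B = length(wins), dims = model$cnn$dims)
  cnn_head_fwd(emb$Y, model$params, dropout = 0, train = FALSE,
               upto = n_true)$y
}
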