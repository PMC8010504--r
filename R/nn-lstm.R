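# Long short-term memory layer, implemented exactly as the model equations
# prescribe: a linear input projection x_t = W_fx fv_t + b_fx feeding gates
#   i_t = sigmoid(W_xi x_t + W_hi h_{t-1} + b_i)
#   g_t = tanh   (W_xg x_t + W_hg h_{t-1} + b_g)
#   f_t = sigmoid(W_xf x_t + W_hf h_{t-1} + b_f)
#   o_t = sigmoid(W_xo x_t + W_ho h_{t-1} + b_o)
#   c_t = f_t * c_{t-1} + i_t * g_t
#   h_t = o_t * tanh(c_t)
# and, for the many-to-one regression head, y = W_hy h_T + b_y.
# Gate weights are stored row-stacked in order (i, g, f, o) so one matrix
# product per step evaluates all four pre-activations.

lstm_layer_init <- function(n_in, n_h) {
  Wx <- rbind(.glorot(n_h, n_in), .glorot(n_h, n_in),
              .glorot(n_h, n_in), .glorot(n_h, n_in))
  Wh <- rbind(.glorot(n_h, n_h), .glorot(n_h, n_h),
              .glorot(n_h, n_h), .glorot(n_h, n_h))
  b <- numeric(4 * n_h)
  b[(2 * n_h + 1):(3 * n_h)] <- 1         # forget-gate bias at 1
  list(Wx = Wx, Wh = Wh, b = b)
}

# X: T x n_in.  Returns list(H = T x n_h, cache).  The recurrence runs in
# compiled code (src/lstm.cpp) with the same gate layout.
lstm_layer_fwd <- function(X, p) {
  out <- lstm_fwd_cpp(X, p$Wx, p$Wh, p$b)
  out$X <- X
  list(H = out$H, cache = out)
}

# Backprop through time.  dH: T x n_h gradients wrt each h_t arriving from
# outside the layer (zero rows except the last for many-to-one).
lstm_layer_bwd <- function(cache, p, dH) {
  bk <- lstm_bwd_cpp(cache$X, p$Wx, p$Wh, p$b, cache$H, cache$C, cache$I,
                     cache$G, cache$Fg, cache$O, dH)
  list(dX = bk$dX, grads = list(Wx = bk$dWx, Wh = bk$dWh, b = as.numeric(bk$db)))
}

# Projection + stacked LSTM layers; many-to-one (returns last hidden state
# of the top layer).  params: list(proj = dense, layers = list of lstm).
lstm_stack_init <- function(n_in, n_h, n_layers) {
  list(proj = dense_init(n_in, n_h),
       layers = lapply(seq_len(n_layers), function(l) lstm_layer_init(n_h, n_h)))
}

lstm_stack_fwd <- function(Fv, p) {
  Xp <- dense_fwd(Fv, p$proj)
  caches <- vector("list", length(p$layers))
  H <- Xp
  for (l in seq_along(p$layers)) {
    out <- lstm_layer_fwd(H, p$layers[[l]])
    caches[[l]] <- out$cache
    H <- out$H
  }
  list(h_last = H[nrow(H), ], H = H,
       cache = list(Fv = Fv, Xp = Xp, layers = caches))
}

# dh_last: gradient wrt the top layer's final hidden state.
# freeze: optional integer layer indices whose weights get zero gradients
# (their dX still flows).
lstm_stack_bwd <- function(cache, p, dh_last, freeze = integer()) {
  L <- length(p$layers)
  Tn <- nrow(cache$Xp)
  n_h <- length(dh_last)
  dH <- matrix(0, Tn, n_h)
  dH[Tn, ] <- dh_last
  grads_layers <- vector("list", L)
  for (l in L:1) {
    bk <- lstm_layer_bwd(cache$layers[[l]], p$layers[[l]], dH)
    grads_layers[[l]] <- if (l %in% freeze) zeros_like(p$layers[[l]]) else bk$grads
    dH <- bk$dX
  }
  pr <- dense_bwd(cache$Fv, dH, p$proj)
  list(dFv = pr$dX,
       grads = list(proj = pr$grads, layers = grads_layers))
}
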