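# Minimal neural-network engine: parameter containers are nested lists of
# matrices/vectors; every layer has an explicit forward (returning a cache)
# and backward (returning input gradients plus parameter gradients shaped
# like the parameters).  Training uses hand-rolled Adam.

# Glorot-uniform initialisation.
.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

dense_init <- function(n_in, n_out) {
  list(W = .glorot(n_out, n_in), b = numeric(n_out))
}

# X: batch x n_in.  Returns batch x n_out.
dense_fwd <- function(X, p) X %*% t(p$W) + rep(p$b, each = nrow(X))

dense_bwd <- function(X, dY, p) {
  list(dX = dY %*% p$W,
       grads = list(W = t(dY) %*% X, b = colSums(dY)))
}

relu_fwd <- function(X) pmax(X, 0)
relu_bwd <- function(X, dY) dY * (X > 0)

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Structure-preserving elementwise map over nested parameter lists.
map_params <- function(f, ...) {
  args <- list(...)
  if (is.null(args[[1]])) return(NULL)
  if (is.list(args[[1]])) {
    out <- lapply(seq_along(args[[1]]), function(i) {
      do.call(map_params, c(list(f), lapply(args, `[[`, i)))
    })
    names(out) <- names(args[[1]])
    out
  } else {
    do.call(f, args)
  }
}

zeros_like <- function(p) map_params(function(x) x * 0, p)

#' @noRd
adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# One Adam step; returns list(params, state).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# Accumulate gradient structures.
add_grads <- function(a, b) map_params(`+`, a, b)
scale_grads <- function(a, s) map_params(function(x) x * s, a)

# Numerically stable softmax cross-entropy.
# logits: batch x K; y: integer class labels (1-based).
# Returns list(loss, dlogits, prob).
softmax_ce <- function(logits, y) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = d / n, prob = p)
}

# Inverted dropout; returns list(Y, mask).  Identity when rate == 0.
dropout_fwd <- function(X, rate, train = TRUE) {
  if (!train || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1, 1 - rate), nrow(X)) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask
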