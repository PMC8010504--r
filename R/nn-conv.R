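# Convolutional layers on stacked-rows batches.
#
# A batch of B equally-sized windows is stored as a (B * prod(dims)) x C
# matrix: for 1D windows dims = T and row (b-1)*T + t holds sample t of
# window b; for 2D (spectrogram) windows dims = c(H, W) and rows are in
# column-major (h fastest) order per window.  Convolutions are evaluated by
# gathering taps into an im2col matrix and a single matrix product, which
# keeps the arithmetic in BLAS.

.idx_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, build) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- build()
    .idx_cache[[key]] <- v
  }
  v
}

# Same-padding gather indices for a conv over stacked rows.
# Returns pad_rows (rows of the padded stack holding real samples, length
# B*N), rows0 (padded row of each output position's first tap), tap_off
# (offset added to rows0 for each of the k taps), n_pad (padded stack size).
.conv_idx <- function(B, dims, k) {
  key <- paste("c", B, paste(dims, collapse = "x"), k, sep = "|")
  .cache_get(key, function() {
    if (length(dims) == 1L) {
      Tn <- dims
      pl <- (k - 1L) %/% 2L
      Tp <- Tn + k - 1L
      pad_rows <- rep((0:(B - 1L)) * Tp, each = Tn) + pl + rep(seq_len(Tn), B)
      rows0 <- rep((0:(B - 1L)) * Tp, each = Tn) + rep(seq_len(Tn), B)
      tap_off <- 0:(k - 1L)
      list(pad_rows = pad_rows, rows0 = rows0, tap_off = tap_off,
           n_pad = B * Tp)
    } else {
      H <- dims[1]; W <- dims[2]
      kh <- k; kw <- k                      # square kernels
      ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
      Hp <- H + kh - 1L; Wp <- W + kw - 1L
      img <- Hp * Wp
      hh <- rep(seq_len(H), W); ww <- rep(seq_len(W), each = H)
      base <- (ww - 1L + pw) * Hp + (hh + ph)       # padded pos of (h, w)
      first <- (ww - 1L) * Hp + hh                  # first tap of output (h, w)
      pad_rows <- rep((0:(B - 1L)) * img, each = H * W) + rep(base, B)
      rows0 <- rep((0:(B - 1L)) * img, each = H * W) + rep(first, B)
      tap_off <- as.integer(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, "+"))
      list(pad_rows = pad_rows, rows0 = rows0, tap_off = tap_off,
           n_pad = B * img)
    }
  })
}

conv_init <- function(k, cin, cout, ndim = 1L) {
  ktot <- if (ndim == 1L) k else k * k
  list(W = .glorot(ktot * cin, cout), b = numeric(cout))
}

# Forward: X (B*N) x cin -> Y (B*N) x cout (same padding, stride 1).
conv_fwd <- function(X, p, B, dims, k) {
  ix <- .conv_idx(B, dims, k)
  cin <- ncol(X)
  Xpad <- matrix(0, ix$n_pad, cin)
  Xpad[ix$pad_rows, ] <- X
  cols <- im2col_gather(Xpad, ix$rows0, ix$tap_off)
  Y <- cols %*% p$W + rep(p$b, each = nrow(X))
  list(Y = Y, cache = list(cols = cols, B = B, dims = dims, k = k, cin = cin))
}

conv_bwd <- function(cache, p, dY) {
  ix <- .conv_idx(cache$B, cache$dims, cache$k)
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(p$W)
  dXpad <- col2im_scatter(dcols, ix$rows0, ix$tap_off, ix$n_pad, cache$cin)
  list(dX = dXpad[ix$pad_rows, , drop = FALSE],
       grads = list(W = dW, b = db))
}

# Disjoint-tile pooling indices: gather matrix (B*No, p^ndim) of source rows,
# cropping any remainder that does not fill a tile.
.pool_idx <- function(B, dims, p) {
  key <- paste("p", B, paste(dims, collapse = "x"), p, sep = "|")
  .cache_get(key, function() {
    if (length(dims) == 1L) {
      Tn <- dims; To <- Tn %/% p
      g <- rep((0:(B - 1L)) * Tn, each = To) + rep((0:(To - 1L)) * p, B)
      idx <- outer(g, seq_len(p), "+")
      list(idx = idx, out_dims = To)
    } else {
      H <- dims[1]; W <- dims[2]
      Ho <- H %/% p; Wo <- W %/% p
      hh <- rep((0:(Ho - 1L)) * p, Wo)
      ww <- rep((0:(Wo - 1L)) * p, each = Ho)
      base <- ww * H + hh                  # top-left corner (0-based)
      tile <- as.integer(outer(1:p, (0:(p - 1L)) * H, "+"))
      g <- rep((0:(B - 1L)) * (H * W), each = Ho * Wo) + rep(base, B)
      idx <- outer(g, tile, "+")
      list(idx = idx, out_dims = c(Ho, Wo))
    }
  })
}

maxpool_fwd <- function(X, B, dims, p) {
  px <- .pool_idx(B, dims, p)
  n_out <- nrow(px$idx); Fc <- ncol(X)
  Y <- matrix(0, n_out, Fc)
  arg <- matrix(0L, n_out, Fc)
  for (f in seq_len(Fc)) {
    V <- matrix(X[, f][px$idx], n_out)
    am <- max.col(V, ties.method = "first")
    Y[, f] <- V[cbind(seq_len(n_out), am)]
    arg[, f] <- px$idx[cbind(seq_len(n_out), am)]
  }
  list(Y = Y, out_dims = px$out_dims,
       cache = list(arg = arg, n_in = nrow(X)))
}

maxpool_bwd <- function(cache, dY) {
  dX <- matrix(0, cache$n_in, ncol(dY))
  for (f in seq_len(ncol(dY))) {
    dX[cache$arg[, f], f] <- dY[, f]
  }
  dX
}

avgpool_fwd <- function(X, B, dims, p) {
  px <- .pool_idx(B, dims, p)
  n_out <- nrow(px$idx); Fc <- ncol(X)
  Y <- matrix(0, n_out, Fc)
  for (f in seq_len(Fc)) {
    Y[, f] <- rowMeans(matrix(X[, f][px$idx], n_out))
  }
  list(Y = Y, out_dims = px$out_dims,
       cache = list(idx = px$idx, n_in = nrow(X)))
}

avgpool_bwd <- function(cache, dY) {
  dX <- matrix(0, cache$n_in, ncol(dY))
  k <- ncol(cache$idx)
  for (j in seq_len(k)) {
    tgt <- cache$idx[, j]
    dX[tgt, ] <- dX[tgt, ] + dY / k
  }
  dX
}

# Global average pooling: (B*N) x F -> B x F.
gap_fwd <- function(X, B) {
  N <- nrow(X) / B
  grp <- rep(seq_len(B), each = N)
  list(Y = rowsum(X, grp) / N, cache = list(B = B, N = N))
}

gap_bwd <- function(cache, dY) {
  dY[rep(seq_len(cache$B), each = cache$N), , drop = FALSE] / cache$N
}

# A conv network is a program: a list of steps, each
# list(op = "conv"|"relu"|"pool"|"avgpool"|"gap", k, cin, cout, p).
# conv_net_init returns per-step params (NULL for parameter-free steps).
conv_net_init <- function(program, ndim) {
  lapply(program, function(st) {
    if (st$op == "conv") conv_init(st$k, st$cin, st$cout, ndim) else NULL
  })
}

conv_net_fwd <- function(program, params, X, B, dims) {
  caches <- vector("list", length(program))
  for (s in seq_along(program)) {
    st <- program[[s]]
    if (st$op == "conv") {
      o <- conv_fwd(X, params[[s]], B, dims, st$k)
      caches[[s]] <- o$cache; X <- o$Y
    } else if (st$op == "relu") {
      caches[[s]] <- X; X <- relu_fwd(X)
    } else if (st$op %in% c("pool", "avgpool")) {
      if (all(dims >= st$p)) {
        o <- if (st$op == "pool") maxpool_fwd(X, B, dims, st$p)
             else avgpool_fwd(X, B, dims, st$p)
        caches[[s]] <- o$cache; X <- o$Y; dims <- o$out_dims
      } else {
        caches[[s]] <- "skip"              # feature map smaller than the tile
      }
    } else if (st$op == "gap") {
      o <- gap_fwd(X, B)
      caches[[s]] <- o$cache; X <- o$Y; dims <- integer()
    }
  }
  list(Y = X, caches = caches)
}

conv_net_bwd <- function(program, params, caches, dY) {
  grads <- vector("list", length(program))
  for (s in rev(seq_along(program))) {
    st <- program[[s]]
    if (st$op == "conv") {
      bk <- conv_bwd(caches[[s]], params[[s]], dY)
      grads[[s]] <- bk$grads; dY <- bk$dX
    } else if (st$op == "relu") {
      dY <- relu_bwd(caches[[s]], dY)
    } else if (st$op %in% c("pool", "avgpool")) {
      if (!identical(caches[[s]], "skip")) {
        dY <- if (st$op == "pool") maxpool_bwd(caches[[s]], dY)
              else avgpool_bwd(caches[[s]], dY)
      }
    } else if (st$op == "gap") {
      dY <- gap_bwd(caches[[s]], dY)
    }
  }
  grads
}
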