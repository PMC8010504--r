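# Training procedures: random-start augmentation, dual-channel LSTM
# training (optionally from pretrained weights with frozen lower layers),
# two-stage CNN-LSTM training, and activity-classification pretraining.
#
# All regressors are trained on z-scored targets with Adam and mini-batches
# of 2 rounds (gradient accumulation over the rounds of a batch, which for
# a many-to-one network matches masked repetition-padded batching);
# per-epoch model selection keeps the weights with the best validation
# Pearson correlation.

#' Random-start sequence augmentation
#'
#' Draws a uniform start index `s` in `0..len-1` and discards everything
#' before it, returning the suffix; applied afresh at every training epoch
#' so the LSTM cannot memorise absolute sequence positions.
#'
#' @param x A matrix (rows = time steps) or list (elements = time steps).
#' @param start Optional fixed 0-based start (mainly for tests); by default
#'   drawn uniformly.
#' @return The suffix of `x` from `start` on.
#' @export
#' @examples
#' nrow(random_start_augment(matrix(0, 48, 2), start = 10))  # 38
random_start_augment <- function(x, start = NULL) {
  len <- if (is.list(x)) length(x) else nrow(x)
  if (len < 2L) return(x)
  if (is.null(start)) start <- sample.int(len, 1L) - 1L
  if (start == 0L) return(x)
  if (is.list(x)) x[(start + 1L):len] else x[(start + 1L):len, , drop = FALSE]
}

# Pearson rho of predictions on a validation set, NA-safe.
.val_rho <- function(y, yhat) {
  if (length(y) < 2L || stats::sd(y) == 0 || stats::sd(yhat) == 0) return(NA_real_)
  stats::cor(y, yhat)
}

#' Train the dual-channel LSTM
#'
#' Adam training of the dual-channel feature LSTM on z-scored labels with
#' random-start augmentation and mini-batches of `batch` rounds; after each
#' epoch the validation Pearson correlation is evaluated and the
#' best-validation weights are kept (not the last epoch's).
#'
#' @param train,val Lists with elements `S`, `L` (lists of normalized
#'   feature matrices) and `y` (z-scored labels).
#' @param spec A [model_spec()].
#' @param epochs,lr,batch Training schedule (defaults 200 epochs, Adam with
#'   learning rate 1e-3, mini-batch 2).
#' @param init Optional initial parameters (e.g. transferred weights).
#' @param freeze LSTM layer indices of the short-term channel excluded from
#'   updates (the channel that carries transferred weights).
#' @param seed Integer seed for initialisation, shuffling and augmentation.
#' @return A list with `params` (best-validation), `best_epoch`, `history`.
#' @export
train_dual_lstm <- function(train, val, spec = model_spec("dual_lstm"),
                            epochs = 200L, lr = 1e-3, batch = 2L,
                            init = NULL, freeze = integer(), seed = 1L) {
  set.seed(seed)
  params <- if (is.null(init)) dual_lstm_init(spec) else init
  opt <- adam_init(params)
  n <- length(train$y)
  best <- list(params = params, rho = -Inf, epoch = 0L)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (bs in split(ord, ceiling(seq_along(ord) / batch))) {
      grads <- NULL
      for (i in bs) {
        nL <- nrow(train$L[[i]])
        sl <- if (nL >= 2L) sample.int(nL, 1L) - 1L else 0L
        S <- train$S[[i]]; L <- train$L[[i]]
        if (sl > 0L) {
          L <- L[(sl + 1L):nL, , drop = FALSE]
          S <- S[(12L * sl + 1L):nrow(S), , drop = FALSE]
        }
        fw <- dual_channel_forward(S, L, params, cache = TRUE)
        bk <- dual_channel_backward(fw$cache, params, fw$y - train$y[i],
                                    freeze_s = freeze)
        grads <- if (is.null(grads)) bk$grads else add_grads(grads, bk$grads)
      }
      st <- adam_step(params, scale_grads(grads, 1 / length(bs)), opt, lr)
      params <- st$params; opt <- st$state
    }
    yv <- vapply(seq_along(val$y), function(i) {
      dual_channel_forward(val$S[[i]], val$L[[i]], params)
    }, numeric(1))
    rho <- .val_rho(val$y, yv)
    history[ep] <- rho
    if (!is.na(rho) && rho > best$rho) {
      best <- list(params = params, rho = rho, epoch = ep)
    }
  }
  if (!is.finite(best$rho)) best$params <- params
  list(params = best$params, best_epoch = best$epoch, history = history)
}

# Embeddings of a round's windows under a (frozen) CNN.
cnn_embed <- function(cnn, params, wins) {
  X <- stack_windows(wins)
  conv_net_fwd(cnn$program, params, X, B = length(wins), dims = cnn$dims)$Y
}

#' Two-stage training of a CNN-LSTM regressor
#'
#' Stage 1 trains the convolutional extractor plus a fully connected head
#' to regress every window to its round's (z-scored) label, keeping the
#' weights with the best validation correlation.  Stage 2 discards the
#' head, freezes the CNN, computes per-window embeddings and trains the
#' LSTM + two fully connected layers on whole rounds (mini-batch 2, Adam,
#' random-start augmentation, dropout on the embeddings), again keeping
#' the best-validation weights.
#'
#' @param train,val Lists with `wins` (list of per-round window lists,
#'   already normalized) and `y` (z-scored labels).
#' @param cnn A builder result from [build_cnn1d()] or [build_cnn2d()].
#' @param spec A [model_spec()].
#' @param stage1_epochs,stage2_epochs,lr Training schedule.
#' @param stage1_batch Windows per stage-1 mini-batch.
#' @param stage1_max_windows Cap on the number of training windows sampled
#'   per stage-1 epoch (plain stochastic subsampling; keeps the per-epoch
#'   cost bounded on large cohorts).
#' @param seed Integer seed.
#' @return A list of class `cnn_lstm_model`: `cnn`, `params` (with `$cnn`
#'   the frozen stage-1 weights), `spec`, per-stage histories.
#' @export
two_stage_train <- function(train, val, cnn, spec, stage1_epochs = 10L,
                            stage2_epochs = 30L, lr = 1e-3,
                            stage1_batch = 16L, stage1_max_windows = 512L,
                            seed = 1L) {
  if (length(val$y) == 0L) stop("two-stage training needs validation rounds")
  set.seed(seed)
  cnn$params <- conv_net_init(cnn$program, cnn$ndim)   # fresh under seed
  head1 <- dense_init(cnn$embed_dim, 1L)

  Xw <- stack_windows(unlist(train$wins, recursive = FALSE))
  n_wins <- vapply(train$wins, length, integer(1))
  yw <- rep(train$y, n_wins)
  nW <- sum(n_wins)
  rows_per <- nrow(Xw) / nW

  s1 <- list(cnn = cnn$params, head = head1)
  opt <- adam_init(s1)
  best1 <- list(params = s1, rho = -Inf, epoch = 0L)
  hist1 <- numeric(stage1_epochs)
  for (ep in seq_len(stage1_epochs)) {
    ord <- sample.int(nW, min(nW, stage1_max_windows))
    for (bs in split(ord, ceiling(seq_along(ord) / stage1_batch))) {
      rows <- as.vector(outer(seq_len(rows_per), (bs - 1L) * rows_per, "+"))
      fw <- conv_net_fwd(cnn$program, s1$cnn, Xw[rows, , drop = FALSE],
                         B = length(bs), dims = cnn$dims)
      yh <- dense_fwd(fw$Y, s1$head)
      dY <- (yh - yw[bs]) / length(bs)
      bh <- dense_bwd(fw$Y, dY, s1$head)
      gc_ <- conv_net_bwd(cnn$program, s1$cnn, fw$caches, bh$dX)
      st <- adam_step(s1, list(cnn = gc_, head = bh$grads), opt, lr)
      s1 <- st$params; opt <- st$state
    }
    yv <- vapply(seq_along(val$y), function(i) {
      mean(dense_fwd(cnn_embed(cnn, s1$cnn, val$wins[[i]]), s1$head))
    }, numeric(1))
    rho <- .val_rho(val$y, yv)
    hist1[ep] <- rho
    if (!is.na(rho) && rho > best1$rho) {
      best1 <- list(params = s1, rho = rho, epoch = ep)
    }
  }
  cnn_params <- best1$params$cnn

  # Stage 2: frozen-CNN embeddings feed the sequence model.
  Etr <- lapply(train$wins, function(w) cnn_embed(cnn, cnn_params, w))
  Eva <- lapply(val$wins, function(w) cnn_embed(cnn, cnn_params, w))
  params <- list(lstm = lstm_stack_init(cnn$embed_dim, spec$n_h,
                                        spec$lstm_layers),
                 fc1 = dense_init(spec$n_h, spec$fc_width),
                 fc2 = dense_init(spec$fc_width, 1L))
  opt <- adam_init(params)
  n <- length(train$y)
  best2 <- list(params = params, rho = -Inf, epoch = 0L)
  hist2 <- numeric(stage2_epochs)
  loss2 <- numeric(stage2_epochs)
  for (ep in seq_len(stage2_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / 2L))) {
      grads <- NULL
      for (i in bs) {
        E <- random_start_augment(Etr[[i]])
        fw <- cnn_head_fwd(E, params, dropout = spec$dropout, train = TRUE)
        ep_loss <- ep_loss + 0.5 * (fw$y - train$y[i])^2
        bk <- cnn_head_bwd(fw$cache, params, fw$y - train$y[i])
        grads <- if (is.null(grads)) bk$grads else add_grads(grads, bk$grads)
      }
      st <- adam_step(params, scale_grads(grads, 1 / length(bs)), opt, lr)
      params <- st$params; opt <- st$state
    }
    loss2[ep] <- ep_loss / n
    yv <- vapply(seq_along(val$y), function(i) {
      cnn_head_fwd(Eva[[i]], params)$y
    }, numeric(1))
    rho <- .val_rho(val$y, yv)
    hist2[ep] <- rho
    if (!is.na(rho) && rho > best2$rho) {
      best2 <- list(params = params, rho = rho, epoch = ep)
    }
  }
  if (!is.finite(best2$rho)) best2$params <- params
  structure(
    list(cnn = cnn,
         params = c(list(cnn = cnn_params), best2$params),
         spec = spec, stage1_history = hist1, stage2_history = hist2,
         stage2_loss = loss2,
         best_epochs = c(stage1 = best1$epoch, stage2 = best2$epoch)),
    class = "cnn_lstm_model")
}

#' Pretrain an LSTM on activity classification
#'
#' Trains projection + stacked LSTM + softmax head to classify short-term
#' feature sequences of the activity corpus; used to initialise the
#' dual-channel LSTM.
#'
#' @param corpus List with `S` (list of 12 x 26 feature sequences) and
#'   `class` (integer labels 1..K).
#' @param spec A [model_spec()].
#' @param epochs,lr,batch Training schedule.
#' @param val_frac Fraction of rounds held out to report accuracy.
#' @param seed Integer seed.
#' @return A list with `stack` (proj + LSTM weights), `head`,
#'   `val_accuracy`, `n_classes`.
#' @export
pretrain_activity_lstm <- function(corpus, spec = model_spec("dual_lstm"),
                                   epochs = 20L, lr = 1e-3, batch = 8L,
                                   val_frac = 0.2, seed = 1L) {
  K <- max(corpus$class)
  if (K < 2L) stop("activity pretraining needs at least 2 classes")
  set.seed(seed)
  n <- length(corpus$class)
  iv <- sample.int(n, max(1L, round(val_frac * n)))
  itr <- setdiff(seq_len(n), iv)
  stack <- lstm_stack_init(ncol(corpus$S[[1]]), spec$n_h, spec$lstm_layers)
  head <- dense_init(spec$n_h, K)
  params <- list(stack = stack, head = head)
  opt <- adam_init(params)
  for (ep in seq_len(epochs)) {
    ord <- sample(itr)
    for (bs in split(ord, ceiling(seq_along(ord) / batch))) {
      grads <- NULL
      for (i in bs) {
        fo <- lstm_stack_fwd(corpus$S[[i]], params$stack)
        logits <- dense_fwd(matrix(fo$h_last, 1), params$head)
        ce <- softmax_ce(logits, corpus$class[i])
        bh <- dense_bwd(matrix(fo$h_last, 1), ce$dlogits, params$head)
        bs_ <- lstm_stack_bwd(fo$cache, params$stack, as.numeric(bh$dX))
        g <- list(stack = bs_$grads, head = bh$grads)
        grads <- if (is.null(grads)) g else add_grads(grads, g)
      }
      st <- adam_step(params, scale_grads(grads, 1 / length(bs)), opt, lr)
      params <- st$params; opt <- st$state
    }
  }
  pred <- vapply(iv, function(i) {
    fo <- lstm_stack_fwd(corpus$S[[i]], params$stack)
    which.max(dense_fwd(matrix(fo$h_last, 1), params$head))
  }, integer(1))
  list(stack = params$stack, head = params$head,
       val_accuracy = mean(pred == corpus$class[iv]), n_classes = K)
}

#' Transfer learning: pretrain on activities, fine-tune on PD rounds
#'
#' Pretrains the LSTM on activity classification
#' ([pretrain_activity_lstm()]), copies the projection and LSTM weights
#' into the short-term channel of the dual-channel network (the pretext
#' task is classification of the same 26-dim short-term features; the
#' 32-dim long-term channel has no pretext counterpart and trains from
#' scratch), freezes every transferred LSTM layer except the last, and
#' fine-tunes the last LSTM layer, the projections and the output layer on
#' the PD rounds.
#'
#' @param corpus Activity corpus as in [pretrain_activity_lstm()].
#' @param train,val PD round sets as in [train_dual_lstm()].
#' @param spec A [model_spec()].
#' @param pretrain_epochs,epochs,lr Schedules for the two phases.
#' @param seed Integer seed.
#' @return As [train_dual_lstm()], plus `pretrained` (the frozen source
#'   weights) and `frozen_layers`.
#' @export
transfer_pretrain_finetune <- function(corpus, train, val,
                                       spec = model_spec("dual_lstm"),
                                       pretrain_epochs = 20L, epochs = 200L,
                                       lr = 1e-3, seed = 1L) {
  if (ncol(corpus$S[[1]]) != ncol(train$S[[1]])) {
    stop("feature dimension mismatch between activity corpus and PD rounds")
  }
  pre <- pretrain_activity_lstm(corpus, spec, epochs = pretrain_epochs,
                                lr = lr, seed = seed)
  set.seed(seed + 1L)
  init <- dual_lstm_init(spec)
  init$s$proj <- pre$stack$proj
  init$s$layers <- pre$stack$layers
  frozen <- seq_len(spec$lstm_layers - 1L)
  fit <- train_dual_lstm(train, val, spec, epochs = epochs, lr = lr,
                         init = init, freeze = frozen, seed = seed + 2L)
  fit$pretrained <- pre
  fit$frozen_layers <- frozen
  fit
}
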