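# Dual-channel LSTM on hand-crafted features: one channel consumes the
# 5-s short-term feature sequence, the other the 1-min long-term sequence;
# the two final hidden states are concatenated and a fully connected layer
# maps the fusion feature to the UPDRS-III estimate.

dual_lstm_init <- function(spec = model_spec("dual_lstm")) {
  list(s = lstm_stack_init(26L, spec$n_h, spec$lstm_layers),
       l = lstm_stack_init(32L, spec$n_h, spec$lstm_layers),
       head = dense_init(2L * spec$n_h, 1L))
}

#' Dual-channel LSTM forward pass
#'
#' Runs the short-term (26-dim) and long-term (32-dim) feature sequences
#' through their respective projection + many-to-one LSTM channels,
#' concatenates the final hidden states and applies the fully connected
#' output layer.
#'
#' @param S `n_short` x 26 short-term feature sequence.
#' @param L `n_long` x 32 long-term feature sequence;
#'   `n_short == 12 * n_long` is required.
#' @param params Parameters from `dual_lstm_init` (or training).
#' @param cache Return forward caches for backpropagation.
#' @return Scalar estimate, or (with `cache = TRUE`) a list `y`, `cache`.
#' @export
dual_channel_forward <- function(S, L, params, cache = FALSE) {
  if (nrow(S) != 12L * nrow(L)) {
    stop("short/long sequence mismatch: need n_short == 12 * n_long, got ",
         nrow(S), " and ", nrow(L))
  }
  os <- lstm_stack_fwd(S, params$s)
  ol <- lstm_stack_fwd(L, params$l)
  fusion <- matrix(c(os$h_last, ol$h_last), 1)
  y <- dense_fwd(fusion, params$head)[1, 1]
  if (!cache) return(y)
  list(y = y, cache = list(os = os, ol = ol, fusion = fusion))
}

# freeze_s: LSTM layer indices kept fixed in the short-term channel
# (transfer learning fine-tunes only its last layer plus the dense layers).
dual_channel_backward <- function(cache, params, dy, freeze_s = integer()) {
  bh <- dense_bwd(cache$fusion, matrix(dy, 1), params$head)
  n_h <- length(cache$os$h_last)
  bs <- lstm_stack_bwd(cache$os$cache, params$s, bh$dX[1, 1:n_h], freeze_s)
  bl <- lstm_stack_bwd(cache$ol$cache, params$l, bh$dX[1, n_h + 1:n_h])
  list(grads = list(s = bs$grads, l = bl$grads, head = bh$grads))
}

#' Average the ensemble members' estimates
#'
#' @param predictions Numeric vector of exactly three member estimates
#'   (dual-channel LSTM with transfer learning, 1D CNN-LSTM, 2D CNN-LSTM).
#' @return Their arithmetic mean.
#' @export
#' @examples
#' ensemble_average(c(10, 20, 30))
ensemble_average <- function(predictions) {
  if (length(predictions) != 3L || anyNA(predictions)) {
    stop("the ensemble averages exactly 3 member predictions")
  }
  mean(predictions)
}
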