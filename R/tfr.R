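# Time-frequency representation feeding the 2D CNN-LSTM.

#' Spectrogram tensor of a 1-min window
#'
#' Short-time Fourier transform of each of the 6 axes with a 5-s
#' (`5 * fs`-sample) Kaiser window (beta = 8), 90% overlap (hop `fs/2`
#' samples), FFT length equal to the window length, magnitude only.  The
#' frequency axis is cropped to 0--16 Hz (81 bins of 0.2 Hz at 64 Hz); the
#' per-axis spectrograms are stacked as channels.
#'
#' @param W A `60 * fs` x 6 signal matrix.
#' @param fs Sampling rate (Hz), default 64.
#' @param beta Kaiser window shape parameter, default 8.
#' @param f_max Frequency crop (Hz), default 16 (just above the 15 Hz
#'   passband edge).
#' @return A frames x freq_bins x 6 array of non-negative magnitudes
#'   (111 x 81 x 6 for a full 1-min window at 64 Hz), with attributes
#'   `hop_s` and `freq` (Hz per bin).
#' @export
#' @examples
#' spg <- compute_spectrogram(matrix(rnorm(3840 * 6), ncol = 6))
#' dim(spg)
compute_spectrogram <- function(W, fs = 64, beta = 8, f_max = 16) {
  win_len <- as.integer(5 * fs)
  hop <- as.integer(win_len / 10)          # 90% overlap
  if (!is.matrix(W) || ncol(W) != 6L || nrow(W) != 60 * fs) {
    stop("spectrogram input must be a ", 60 * fs, " x 6 matrix")
  }
  n <- nrow(W)
  n_frames <- (n - win_len) %/% hop + 1L
  kw <- signal::kaiser(win_len, beta)
  freq <- (seq_len(win_len) - 1L) * fs / win_len
  keep <- which(freq <= f_max)
  out <- array(0, dim = c(n_frames, length(keep), 6L))
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win_len), starts, "+")      # win_len x n_frames
  for (ch in 1:6) {
    seg <- matrix(W[idx, ch], nrow = win_len) * kw
    out[, , ch] <- t(abs(stats::mvfft(seg))[keep, , drop = FALSE])
  }
  attr(out, "hop_s") <- hop / fs
  attr(out, "freq") <- freq[keep]
  out
}
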