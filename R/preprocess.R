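# Preprocessing: band-pass prefilter, rate conversion, exam-segment
# exclusion, round selection and windowing.

.bp_cache <- new.env(parent = emptyenv())

#' FIR band-pass design with calibrated half-power points
#'
#' Designs a linear-phase, Hamming-window FIR band-pass whose measured
#' -3 dB (half-power) frequencies sit at `lo` and `hi`.  The window method
#' places roughly -6 dB at the nominal band edges, so the edges are tuned
#' numerically until the measured half-power points match the targets.
#'
#' @param fs Sampling rate (Hz).
#' @param lo,hi Target half-power frequencies (Hz), default 0.5 and 15.
#' @param taps Filter length (odd), default 513.
#' @return Numeric vector of filter coefficients with attributes
#'   `halfpower` (the measured -3 dB points) and `fs`.
#' @export
design_bandpass <- function(fs, lo = 0.5, hi = 15, taps = 513L) {
  key <- paste(fs, lo, hi, taps, sep = "|")
  if (!is.null(.bp_cache[[key]])) return(.bp_cache[[key]])
  stopifnot(taps %% 2L == 1L, hi < fs / 2, lo > 0, lo < hi)
  edges <- c(lo, hi)
  for (iter in 1:6) {
    b <- signal::fir1(taps - 1L, edges / (fs / 2), type = "pass",
                      window = signal::hamming(taps))
    hp <- .measure_halfpower(b, fs, lo, hi)
    err <- c(lo, hi) - hp
    if (all(abs(err) < 0.005)) break
    edges <- edges + err
  }
  attr(b, "halfpower") <- hp
  attr(b, "fs") <- fs
  .bp_cache[[key]] <- b
  b
}

# Magnitude response of an FIR filter on a frequency grid.
.fir_mag <- function(b, f, fs) {
  k <- seq_along(b) - 1L
  abs(exp(-2i * pi * outer(f / fs, k)) %*% b)[, 1]
}

# Locate the two half-power crossings of a band-pass around lo and hi.
.measure_halfpower <- function(b, fs, lo, hi) {
  ref <- .fir_mag(b, sqrt(lo * hi), fs) / sqrt(2)   # mid-band gain - 3 dB
  g <- function(f) .fir_mag(b, f, fs) - ref
  lo_hp <- stats::uniroot(g, c(max(lo / 4, 1e-3), sqrt(lo * hi)),
                          tol = 1e-6)$root
  hi_hp <- stats::uniroot(g, c(sqrt(lo * hi), min(hi * 1.5, fs / 2 - 1e-3)),
                          tol = 1e-6)$root
  c(lo_hp, hi_hp)
}

#' Band-pass prefilter with group-delay compensation
#'
#' Applies the calibrated 0.5--15 Hz FIR band-pass ([design_bandpass()]) by
#' full convolution and removes the (`taps`-1)/2-sample group delay, so the
#' output is time-aligned with, and the same length as, the input.
#'
#' @param x Numeric vector, or a matrix filtered column-wise.
#' @param fs Sampling rate (Hz), >= 32.
#' @param lo,hi Half-power band edges (Hz).
#' @param taps Filter length; the signal must be longer than this.
#' @return Filtered signal of the same shape as `x`.
#' @export
#' @examples
#' y <- bandpass_filter(sin(2 * pi * 5 * (0:1279) / 64), fs = 64)
bandpass_filter <- function(x, fs, lo = 0.5, hi = 15, taps = 513L) {
  if (fs < 32) stop("fs must be >= 32 Hz")
  if (is.matrix(x)) {
    return(apply(x, 2, bandpass_filter, fs = fs, lo = lo, hi = hi,
                 taps = taps))
  }
  n <- length(x)
  if (n <= taps) {
    stop("signal too short to band-pass filter: need more than ", taps,
         " samples, got ", n)
  }
  b <- design_bandpass(fs, lo, hi, taps)
  gd <- (taps - 1L) %/% 2L
  y <- stats::convolve(x, rev(b), type = "open")   # length n + taps - 1
  y[(gd + 1L):(gd + n)]
}

#' Resample a signal to 64 Hz
#'
#' Anti-aliased polyphase rational rate conversion down to the pipeline's
#' 64 Hz working rate.  Output length is `round(length(x) * 64 / fs_in)`.
#'
#' @param x Numeric vector or matrix (columns are channels).
#' @param fs_in Input sampling rate (Hz); must be >= 64 (no upsampling).
#' @return The signal at 64 Hz.
#' @export
resample_to_64 <- function(x, fs_in) {
  if (fs_in < 64) {
    stop("resample_to_64 only downsamples: fs_in must be >= 64, got ", fs_in)
  }
  if (fs_in == 64) return(x)
  if (is.matrix(x)) {
    out <- apply(x, 2, resample_to_64, fs_in = fs_in)
    colnames(out) <- colnames(x)
    return(out)
  }
  scale <- 1
  while (abs(fs_in * scale - round(fs_in * scale)) > 1e-9 && scale < 1e6) {
    scale <- scale * 10
  }
  p <- 64 * scale; q <- round(fs_in * scale)
  g <- .gcd(p, q)
  y <- signal::resample(x, p / g, q / g)
  n_out <- round(length(x) * 64 / fs_in)
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(y[length(y)], n_out - length(y)))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Remove flagged examination intervals from a recording
#'
#' Deletes the samples falling in half-open `[start, end)` exam intervals
#' (seconds from recording start) and returns the remaining stretches as
#' separate segments -- data on the two sides of a removed exam is never
#' concatenated.
#'
#' @param X Samples x channels signal matrix.
#' @param fs Sampling rate (Hz).
#' @param exam_intervals Two-column matrix (or NULL) of `[start, end)` times
#'   in seconds; intervals must be non-overlapping and within the recording.
#' @return A tibble of segments with `t_start` (s) and `X` (list of
#'   matrices); zero rows (with a warning) if the exams cover everything.
#' @export
exclude_exam_segments <- function(X, fs, exam_intervals = NULL) {
  n <- nrow(X)
  span <- n / fs
  if (is.null(exam_intervals) || nrow(exam_intervals) == 0L) {
    return(tibble::tibble(t_start = 0, X = list(X)))
  }
  iv <- exam_intervals[order(exam_intervals[, 1]), , drop = FALSE]
  if (any(iv[, 2] <= iv[, 1])) stop("exam intervals must have start < end")
  if (any(iv[, 1] < 0) || any(iv[, 2] > span + 1e-9)) {
    stop("exam intervals must lie within the recording span of ", span, " s")
  }
  if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2])) {
    stop("exam intervals must not overlap")
  }
  keep_start <- c(0, iv[, 2])
  keep_end <- c(iv[, 1], span)
  out <- list()
  for (k in seq_along(keep_start)) {
    i0 <- ceiling(keep_start[k] * fs - 1e-9) + 1L   # first kept sample (1-based)
    i1 <- ceiling(keep_end[k] * fs - 1e-9)          # last kept sample
    if (i1 >= i0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        t_start = (i0 - 1L) / fs, X = list(X[i0:i1, , drop = FALSE]))
    }
  }
  if (length(out) == 0L) {
    warning("exam intervals cover the whole recording; no data remains")
    return(tibble::tibble(t_start = numeric(), X = list()))
  }
  dplyr::bind_rows(out)
}

#' Select labelled rounds near each assessment
#'
#' Cuts one round per clinical assessment from the exam-free segments: the
#' round starts at (or as near as possible to) the assessment time, extends
#' forward up to `max_duration_s`, and never crosses a segment boundary.
#' If fewer than 60 s are available ahead of the assessment, the round is
#' taken backwards, ending at the assessment.  Each round is labelled with
#' that (nearest) assessment's total.
#'
#' @param segments Segment tibble from [exclude_exam_segments()].
#' @param assessments Tibble with `time` (s) and `total` (UPDRS-III score).
#' @param fs Sampling rate (Hz).
#' @param max_duration_s Duration cap per round (default 600 s = 10 min).
#' @return A tibble of rounds: `round`, `t_start`, `duration_s`,
#'   `updrs_total`, `X` (list of matrices); empty (with a warning) if no
#'   segment offers 60 s.
#' @export
select_rounds <- function(segments, assessments, fs, max_duration_s = 600) {
  out <- list()
  for (a in seq_len(nrow(assessments))) {
    at <- assessments$time[a]
    best <- NULL
    for (k in seq_len(nrow(segments))) {
      s0 <- segments$t_start[k]
      s1 <- s0 + nrow(segments$X[[k]]) / fs
      dist <- max(0, s0 - at, at - s1)
      if (is.null(best) || dist < best$dist) best <- list(k = k, s0 = s0, s1 = s1, dist = dist)
    }
    if (is.null(best)) next
    start_t <- min(max(at, best$s0), best$s1)
    end_t <- min(start_t + max_duration_s, best$s1)
    if (end_t - start_t < 60) {                      # not enough data ahead
      end_t <- start_t
      start_t <- max(best$s0, end_t - max_duration_s)
    }
    if (end_t - start_t < 60) next
    seg <- segments$X[[best$k]]
    i0 <- round((start_t - best$s0) * fs) + 1L
    i1 <- round((end_t - best$s0) * fs)
    out[[length(out) + 1L]] <- tibble::tibble(
      round = a, t_start = start_t, duration_s = (i1 - i0 + 1L) / fs,
      updrs_total = assessments$total[a],
      X = list(seg[i0:i1, , drop = FALSE]))
  }
  if (length(out) == 0L) {
    warning("no segment of at least 60 s available; no rounds selected")
    return(tibble::tibble(round = integer(), t_start = numeric(),
                          duration_s = numeric(), updrs_total = numeric(),
                          X = list()))
  }
  dplyr::bind_rows(out)
}

#' Split a round into aligned short and long windows
#'
#' Cuts non-overlapping, left-aligned 1-min long windows (`60 * fs` samples)
#' and splits each into 12 consecutive non-overlapping 5-s short windows
#' (`5 * fs` samples); any trailing partial minute is discarded.
#'
#' @param X Samples x 6 signal matrix of one round.
#' @param fs Sampling rate (Hz); the pipeline operates at 64 Hz.
#' @return A list of class `window_set`: `short` and `long` are lists of
#'   signal matrices, `n_short == 12 * n_long`.
#' @export
#' @examples
#' ws <- segment_windows(matrix(rnorm(3840 * 6), ncol = 6), fs = 64)
#' c(ws$n_long, ws$n_short)
segment_windows <- function(X, fs = 64) {
  long_len <- as.integer(60 * fs)
  short_len <- as.integer(5 * fs)
  if (nrow(X) < long_len) {
    stop("round shorter than one minute (", nrow(X), " < ", long_len,
         " samples); cannot window")
  }
  n_long <- nrow(X) %/% long_len
  long <- vector("list", n_long)
  short <- vector("list", 12L * n_long)
  for (l in seq_len(n_long)) {
    off <- (l - 1L) * long_len
    long[[l]] <- X[(off + 1L):(off + long_len), , drop = FALSE]
    for (s in 1:12) {
      so <- off + (s - 1L) * short_len
      short[[(l - 1L) * 12L + s]] <- X[(so + 1L):(so + short_len), , drop = FALSE]
    }
  }
  structure(list(short = short, long = long,
                 n_short = length(short), n_long = n_long, fs = fs),
            class = "window_set")
}

#' Per-dimension z-score statistics
#'
#' @param x Numeric matrix (or data frame of numerics); statistics are
#'   computed per column.  Compute these on training-fold data only.
#' @return A list with `mean` and `sd` vectors.
#' @export
norm_stats <- function(x) {
  x <- as.matrix(x)
  list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
}

#' Z-score data with training-fold statistics
#'
#' Centres and scales each dimension by the supplied training statistics;
#' zero-variance dimensions map to 0 rather than dividing by zero.
#'
#' @param x Numeric matrix or vector.
#' @param stats A list from [norm_stats()] (computed on the training fold).
#' @return Normalized data of the same shape.
#' @export
normalize <- function(x, stats) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean)) {
    stop("normalization statistics have ", length(stats$mean),
         " dimensions but the data has ", ncol(x))
  }
  sdv <- stats$sd
  sdv[!is.finite(sdv)] <- 0
  out <- sweep(x, 2, stats$mean)
  out <- sweep(out, 2, ifelse(sdv > 0, sdv, 1), "/")
  out[, sdv == 0] <- 0
  if (vec) out[, 1] else out
}
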