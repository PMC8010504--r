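# Hand-crafted feature operators on single-axis angular-velocity windows.
#
# Spectral conventions: one-sided, rectangular-window periodogram of the
# (already band-passed) window with bin width fs/N, scaled so the full-band
# sum equals the time-domain mean square (Parseval).  Feature-band limits
# are inclusive.  Degenerate inputs (zero or constant windows) follow
# explicit zero conventions so feature vectors stay finite.

#' One-sided periodogram
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @return A list with `freq` (Hz, from 0 to Nyquist) and `power`
#'   (rad^2/s^2 per bin); `sum(power)` equals `mean(x^2)`.
#' @export
periodogram_os <- function(x, fs) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  P <- abs(fft(x))^2 / n^2
  half <- floor(n / 2)
  idx <- 1:(half + 1L)
  pow <- P[idx]
  dbl <- 2:(if (n %% 2 == 0) half else half + 1L)   # bins with a mirror image
  pow[dbl] <- 2 * pow[dbl]
  list(freq = (idx - 1L) * fs / n, power = pow)
}

#' Signal power in a frequency band
#'
#' Sums the one-sided periodogram over bins with `f_lo <= f <= f_hi`.
#'
#' @param x Numeric vector.
#' @param f_lo,f_hi Band limits (Hz), `0 <= f_lo < f_hi <= fs/2`.
#' @param fs Sampling rate (Hz).
#' @return Band power in rad^2/s^2.
#' @export
#' @examples
#' band_power(sin(2 * pi * 5 * (0:319) / 64), 4, 6, 64)  # ~ 0.5 = A^2/2
band_power <- function(x, f_lo, f_hi, fs) {
  if (length(x) == 0L) stop("empty signal")
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= fs / 2)) {
    stop("need 0 <= f_lo < f_hi <= fs/2")
  }
  p <- periodogram_os(x, fs)
  sum(p$power[p$freq >= f_lo & p$freq <= f_hi])
}

#' Percentage of power above a frequency threshold
#'
#' `100 * power(f > f_thresh) / power(0.5 Hz .. Nyquist)`; a zero-power
#' signal returns 0 by convention.
#'
#' @inheritParams band_power
#' @param f_thresh Threshold frequency (Hz), default 4.
#' @return Percentage in \[0, 100\].
#' @export
percent_power_above <- function(x, f_thresh = 4, fs = 64) {
  p <- periodogram_os(x, fs)
  total <- sum(p$power[p$freq >= 0.5])
  if (total <= 0) return(0)
  100 * sum(p$power[p$freq > f_thresh]) / total
}

# Autocorrelation (biased, normalized to 1 at lag 0) via FFT.
.autocorr <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  v <- sum(x^2)
  if (v <= 0) return(NULL)
  m <- 2L^ceiling(log2(2L * n))
  ac <- Re(fft(abs(fft(c(x, rep(0, m - n))))^2, inverse = TRUE))[1:n] / m
  ac / ac[1]
}

# Local maxima of `y` with topographic prominence >= prom.  Prominence of a
# peak is its height minus the higher of the two deepest valleys separating
# it from higher terrain on each side (edge-bounded where no higher terrain
# exists).
.find_peaks <- function(y, prom = 0.05) {
  n <- length(y)
  if (n < 3L) return(integer())
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  if (length(cand) == 0L) return(integer())
  keep <- logical(length(cand))
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    j <- i; vmin_l <- y[i]
    while (j > 1L && y[j] <= y[i]) { j <- j - 1L; vmin_l <- min(vmin_l, y[j]) }
    j <- i; vmin_r <- y[i]
    while (j < n && y[j] <= y[i]) { j <- j + 1L; vmin_r <- min(vmin_r, y[j]) }
    keep[ii] <- (y[i] - max(vmin_l, vmin_r)) >= prom
  }
  cand[keep]
}

#' Autocorrelation peak statistics
#'
#' Normalized autocorrelation (1 at lag zero); peaks are local maxima at
#' lags >= 1 sample with topographic prominence >= `prom`.  Returns the
#' amplitude and lag (s) of the smallest-lag peak, the peak count, and the
#' summed peak amplitudes.  Constant or zero windows return all zeros.
#'
#' @param x Numeric vector (>= 64 samples for meaningful output).
#' @param fs Sampling rate (Hz).
#' @param prom Prominence threshold, default 0.05.
#' @return Named numeric vector `(first_peak_amp, first_peak_lag_s, n_peaks,
#'   sum_peak_amps)`.
#' @export
autocorr_peak_stats <- function(x, fs, prom = 0.05) {
  zero <- c(first_peak_amp = 0, first_peak_lag_s = 0, n_peaks = 0,
            sum_peak_amps = 0)
  ac <- .autocorr(x)
  if (is.null(ac)) return(zero)
  pk <- .find_peaks(ac, prom)
  pk <- pk[pk >= 2L]                      # lags >= 1 sample
  if (length(pk) == 0L) return(zero)
  c(first_peak_amp = ac[pk[1]], first_peak_lag_s = (pk[1] - 1L) / fs,
    n_peaks = length(pk), sum_peak_amps = sum(ac[pk]))
}

#' Spectral entropy over the 0.5--15 Hz band
#'
#' Shannon entropy of the periodogram normalized to a probability
#' distribution over the 0.5--15 Hz bins, divided by `log(#bins)` so the
#' result lies in \[0, 1\] (0 for a zero-power signal by convention).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @return Normalized spectral entropy in \[0, 1\].
#' @export
spectral_entropy <- function(x, fs) {
  p <- periodogram_os(x, fs)
  sel <- p$freq >= 0.5 & p$freq <= 15
  pw <- p$power[sel]
  tot <- sum(pw)
  if (tot <= 0) return(0)
  pr <- pw[pw > 0] / tot
  -sum(pr * log(pr)) / log(sum(sel))
}

#' Dominant and secondary spectral peaks
#'
#' The dominant frequency `f1` is the periodogram argmax over 0.5--15 Hz;
#' the secondary `f2` is the highest local maximum at least 0.5 Hz away from
#' `f1` (ties to the lower frequency).  Powers are the bin values.  Local
#' maxima below 1e-10 of the dominant power are numerical leakage, not
#' peaks.  With no secondary peak `(f2, p2) = (0, 0)`; a zero signal gives
#' all zeros.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector `(f1, p1, f2, p2)`.
#' @export
dominant_secondary_freqs <- function(x, fs) {
  p <- periodogram_os(x, fs)
  sel <- which(p$freq >= 0.5 & p$freq <= 15)
  pw <- p$power[sel]; fr <- p$freq[sel]
  if (sum(pw) <= 0) return(c(f1 = 0, p1 = 0, f2 = 0, p2 = 0))
  i1 <- which.max(pw)                               # ties -> lowest frequency
  m <- length(pw)
  loc <- which(pw > c(-Inf, pw[-m]) & pw >= c(pw[-1], -Inf))
  loc <- loc[abs(fr[loc] - fr[i1]) >= 0.5 & pw[loc] > 1e-10 * pw[i1]]
  if (length(loc) == 0L) {
    return(c(f1 = fr[i1], p1 = pw[i1], f2 = 0, p2 = 0))
  }
  i2 <- loc[which.max(pw[loc])]
  c(f1 = fr[i1], p1 = pw[i1], f2 = fr[i2], p2 = pw[i2])
}

#' Zero-lag cross-correlation of two axes
#'
#' Pearson correlation of two equal-length axis signals; if either is
#' constant the correlation is 0 by convention.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
axis_crosscorr <- function(x, y) {
  if (length(x) != length(y)) stop("axis signals must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Mean absolute angular jerk
#'
#' Mean absolute second-order finite difference of the angular-velocity
#' signal scaled by `fs^2` -- an angular-jerk proxy in rad/s^3.
#'
#' @param x Numeric vector (length >= 3).
#' @param fs Sampling rate (Hz).
#' @return Mean absolute jerk (rad/s^3).
#' @export
mean_abs_jerk <- function(x, fs) {
  if (length(x) < 3L) return(0)
  mean(abs(diff(x, differences = 2L))) * fs^2
}

#' Peak-to-peak amplitude
#'
#' @param x Nonempty numeric vector.
#' @return `max(x) - min(x)` (rad/s).
#' @export
peak_to_peak <- function(x) {
  if (length(x) == 0L) stop("empty signal")
  max(x) - min(x)
}

#' Histogram Shannon entropy
#'
#' Entropy (nats) of a 16-equal-width-bin histogram over the window's own
#' range; a constant window has entropy 0 by convention.
#'
#' @param x Nonempty numeric vector.
#' @param bins Number of histogram bins, default 16.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(x, bins = 16L) {
  if (length(x) == 0L) stop("empty signal")
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  cnt <- tabulate(pmin(bins, 1L + floor((x - rng[1]) / diff(rng) * bins)),
                  nbins = bins)
  pr <- cnt[cnt > 0] / length(x)
  -sum(pr * log(pr))
}

#' Sample entropy
#'
#' Standard sample entropy with embedding dimension `m`, tolerance
#' `r` (default `0.2 * sd(x)`), Chebyshev distance, self-matches excluded.
#' A constant window returns 0; when no template pair matches (the
#' statistic is undefined) the value is capped at
#' `log((n - m) * (n - m - 1))` to keep features finite.
#'
#' @param x Numeric vector (length >= 100 recommended).
#' @param m Embedding dimension, default 2.
#' @param r Tolerance; default `0.2 * sd(x)`.
#' @return Sample entropy (>= 0).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n <= m + 1L || stats::sd(x) == 0) return(0)
  cnt <- sampen_counts(x, as.integer(m), r)
  cap <- log((n - m) * (n - m - 1))
  if (cnt$B == 0) return(cap)
  if (cnt$A == 0) return(cap)
  min(cap, -log(cnt$A / cnt$B))
}

#' Gini index of absolute amplitudes
#'
#' Sparsity of the window's absolute values:
#' `G = sum_i (2i - n - 1) a_(i) / (n sum a)` over the ascending sorted
#' absolute values; an all-zero window returns 0.
#'
#' @param x Nonempty numeric vector.
#' @return Gini index in \[0, 1).
#' @export
#' @examples
#' gini_index(c(0, 0, 0, 1))  # 0.75
gini_index <- function(x) {
  if (length(x) == 0L) stop("empty signal")
  a <- sort(abs(x))
  n <- length(a)
  s <- sum(a)
  if (s == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * a) / (n * s)
}

#' First four population moments
#'
#' Mean, population standard deviation, skewness and excess kurtosis; a
#' constant window returns `(c, 0, 0, 0)`.
#'
#' @param x Numeric vector (length >= 4 for meaningful higher moments).
#' @return Named numeric vector `(mean, sd, skewness, excess_kurtosis)`.
#' @export
moment_stats <- function(x) {
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v <= 0) return(c(mean = mu, sd = 0, skewness = 0, excess_kurtosis = 0))
  c(mean = mu, sd = sqrt(v),
    skewness = mean((x - mu)^3) / v^1.5,
    excess_kurtosis = mean((x - mu)^4) / v^2 - 3)
}
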