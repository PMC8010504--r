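# Assembly of the 26-dim short-term and 32-dim long-term feature vectors:
# per sensor the per-axis features are computed on x, y, z and arithmetic-
# averaged across axes (the three pairwise axis cross-correlations average
# into one value), then wrist and ankle blocks are concatenated.

.short_feature_base <- c(
  "bp_4_6", "pct_gt4", "bp_05_15",
  "ac_first_amp", "ac_first_lag", "ac_n", "ac_sum",
  "spec_entropy", "f1", "p1", "f2", "p2", "axis_xcorr"
)

.long_feature_base <- c(
  "jerk", "p2p", "bp_1_4", "bp_05_15", "shannon_h", "sd",
  "ac_n", "ac_sum", "gini", "sampen",
  "mean", "skew", "kurt", "spec_entropy", "f1", "p1"
)

#' Short-term feature names (26)
#' @return Character vector of the 26 short-term feature names.
#' @export
short_feature_names <- function() {
  c(paste0("wrist_", .short_feature_base), paste0("ankle_", .short_feature_base))
}

#' Long-term feature names (32)
#' @return Character vector of the 32 long-term feature names.
#' @export
long_feature_names <- function() {
  c(paste0("wrist_", .long_feature_base), paste0("ankle_", .long_feature_base))
}

# 12 axis-averaged short-term features of one 3-axis sensor + 1 mean
# pairwise cross-correlation = 13 (39 per-axis values before averaging).
.short_sensor_features <- function(A, fs) {
  per_axis <- sapply(1:3, function(j) {
    x <- A[, j]
    ac <- autocorr_peak_stats(x, fs)
    ds <- dominant_secondary_freqs(x, fs)
    c(band_power(x, 4, 6, fs),
      percent_power_above(x, 4, fs),
      band_power(x, 0.5, 15, fs),
      ac, spectral_entropy(x, fs), ds)
  })
  xc <- mean(c(axis_crosscorr(A[, 1], A[, 2]),
               axis_crosscorr(A[, 1], A[, 3]),
               axis_crosscorr(A[, 2], A[, 3])))
  c(rowMeans(per_axis), xc)
}

.long_sensor_features <- function(A, fs) {
  per_axis <- sapply(1:3, function(j) {
    x <- A[, j]
    ac <- autocorr_peak_stats(x, fs)
    ms <- moment_stats(x)
    ds <- dominant_secondary_freqs(x, fs)
    c(mean_abs_jerk(x, fs),
      peak_to_peak(x),
      band_power(x, 1, 4, fs),
      band_power(x, 0.5, 15, fs),
      shannon_entropy(x),
      ms["sd"],
      ac["n_peaks"], ac["sum_peak_amps"],
      gini_index(x),
      sample_entropy(x),
      ms["mean"], ms["skewness"], ms["excess_kurtosis"],
      spectral_entropy(x, fs),
      ds["f1"], ds["p1"])
  })
  rowMeans(per_axis)
}

#' Extract the 26 short-term features of one 5-s window
#'
#' Computes 13 per-axis-family features per sensor (12 spectral/temporal
#' features averaged over the x, y, z axes, plus the mean of the three
#' pairwise axis cross-correlations) and concatenates wrist then ankle.
#'
#' @param W A `5 * fs` x 6 matrix (wrist x/y/z, ankle x/y/z).
#' @param fs Sampling rate (Hz), default 64.
#' @return Named numeric vector of length 26.
#' @export
extract_short_features <- function(W, fs = 64) {
  if (!is.matrix(W) || ncol(W) != 6L || nrow(W) != 5 * fs) {
    stop("short window must be a ", 5 * fs, " x 6 matrix")
  }
  setNames(c(.short_sensor_features(W[, 1:3, drop = FALSE], fs),
             .short_sensor_features(W[, 4:6, drop = FALSE], fs)),
           short_feature_names())
}

#' Extract the 32 long-term features of one 1-min window
#'
#' Computes 16 axis-averaged features per sensor (jerk, peak-to-peak, band
#' powers, entropies, moments, autocorrelation peak counts, Gini index,
#' sample entropy, dominant frequency and power) and concatenates wrist
#' then ankle.
#'
#' @param W A `60 * fs` x 6 matrix (wrist x/y/z, ankle x/y/z).
#' @param fs Sampling rate (Hz), default 64.
#' @return Named numeric vector of length 32.
#' @export
extract_long_features <- function(W, fs = 64) {
  if (!is.matrix(W) || ncol(W) != 6L || nrow(W) != 60 * fs) {
    stop("long window must be a ", 60 * fs, " x 6 matrix")
  }
  setNames(c(.long_sensor_features(W[, 1:3, drop = FALSE], fs),
             .long_sensor_features(W[, 4:6, drop = FALSE], fs)),
           long_feature_names())
}

#' Extract aligned short- and long-term feature sequences for one round
#'
#' Windows the round ([segment_windows()]) and stacks per-window feature
#' vectors: `S` is `n_short` x 26 and `L` is `n_long` x 32 with
#' `n_short == 12 * n_long`.
#'
#' @param X Samples x 6 signal matrix of one (already filtered) round.
#' @param fs Sampling rate (Hz), default 64.
#' @return A list with matrices `S` and `L`.
#' @export
extract_round_features <- function(X, fs = 64) {
  ws <- segment_windows(X, fs)
  S <- t(vapply(ws$short, extract_short_features, numeric(26), fs = fs))
  L <- t(vapply(ws$long, extract_long_features, numeric(32), fs = fs))
  list(S = S, L = L)
}

#' Add feature sequences to a cohort
#'
#' Band-pass filters each round's signals and appends the short-term (`S`)
#' and long-term (`L`) feature-sequence matrices plus the spectrogram
#' tensor list (`SPG`) as list-columns.
#'
#' @param cohort A cohort tibble from [synth_cohort()] (columns `X`, `fs`).
#' @param filter Apply the 0.5--15 Hz prefilter first (default TRUE).
#' @param spectrograms Also compute per-1-min-window spectrogram tensors.
#' @return The cohort tibble with list-columns `Xf`, `S`, `L` and
#'   (optionally) `SPG`.
#' @export
#' @examples
#' \donttest{
#' coh <- synth_cohort(cohort_config_smoke(seed = 1))
#' coh <- cohort_features(coh[1:2, ])
#' dim(coh$S[[1]])
#' }
cohort_features <- function(cohort, filter = TRUE, spectrograms = TRUE) {
  stopifnot(all(c("X", "fs") %in% names(cohort)))
  n <- nrow(cohort)
  Xf <- vector("list", n); S <- vector("list", n); L <- vector("list", n)
  SPG <- vector("list", n)
  for (i in seq_len(n)) {
    fs <- cohort$fs[i]
    Xi <- if (filter) bandpass_filter(cohort$X[[i]], fs) else cohort$X[[i]]
    Xf[[i]] <- Xi
    fr <- extract_round_features(Xi, fs)
    S[[i]] <- fr$S; L[[i]] <- fr$L
    if (spectrograms) {
      ws <- segment_windows(Xi, fs)
      SPG[[i]] <- lapply(ws$long, compute_spectrogram, fs = fs)
    }
  }
  cohort$Xf <- Xf; cohort$S <- S; cohort$L <- L
  if (spectrograms) cohort$SPG <- SPG
  cohort
}

#' Add short-term feature sequences to an activity corpus
#'
#' Band-pass filters each 1-min activity round and extracts its 12 x 26
#' short-term feature sequence -- the representation shared with the PD
#' rounds, whose axis-averaging removes sensor-orientation differences
#' between the two datasets.
#'
#' @param corpus Tibble from [synth_activity_corpus()].
#' @param filter Apply the 0.5--15 Hz prefilter first (default TRUE).
#' @return The corpus with an `S` list-column (12 x 26 matrices).
#' @export
activity_features <- function(corpus, filter = TRUE) {
  corpus$S <- lapply(seq_len(nrow(corpus)), function(i) {
    fs <- corpus$fs[i]
    X <- corpus$X[[i]]
    if (fs > 64) { X <- resample_to_64(X, fs); fs <- 64 }
    if (filter) X <- bandpass_filter(X, fs)
    extract_round_features(X, fs)$S
  })
  corpus
}

#' Feature sequences as a long tibble
#'
#' One row per window with identifying columns and the named feature
#' columns; suitable for CSV export.
#'
#' @param cohort A cohort with feature list-columns (see [cohort_features()]).
#' @param which `"short"` or `"long"`.
#' @return A tibble with `subject`, `round`, `window`, `t_window` and 26 or
#'   32 feature columns.
#' @export
features_to_tibble <- function(cohort, which = c("short", "long")) {
  which <- match.arg(which)
  col <- if (which == "short") "S" else "L"
  step <- if (which == "short") 5 else 60
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    M <- cohort[[col]][[i]]
    dplyr::bind_cols(
      tibble::tibble(subject = cohort$subject[i], round = cohort$round[i],
                     window = seq_len(nrow(M)),
                     t_window = (seq_len(nrow(M)) - 1) * step),
      tibble::as_tibble(M))
  })
}
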