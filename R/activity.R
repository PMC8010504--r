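# Synthetic activity-labelled corpus used as the transfer-learning pretext
# task, standing in for a public activity-monitoring dataset.

# Class-specific signal signatures: amplitude scales (rad/s) for wrist and
# ankle, a locomotion/gesture periodicity (Hz; 0 = aperiodic posture), and a
# relative harmonic content.  Sedentary postures have near-zero power;
# locomotion has strong 1.5-2.5 Hz ankle periodicity.
.activity_classes <- tibble::tribble(
  ~activity,            ~wrist_amp, ~ankle_amp, ~freq, ~harm,
  "lying",                    0.01,       0.01,   0.0,  0.0,
  "sitting",                  0.04,       0.02,   0.0,  0.0,
  "standing",                 0.06,       0.03,   0.0,  0.0,
  "watching_tv",              0.08,       0.02,   0.0,  0.0,
  "computer_work",            0.15,       0.02,   0.0,  0.0,
  "ironing",                  0.50,       0.05,   0.8,  0.3,
  "vacuum_cleaning",          0.60,       0.30,   1.0,  0.3,
  "walking",                  0.80,       1.50,   1.9,  0.4,
  "nordic_walking",           1.00,       1.60,   2.0,  0.4,
  "ascending_stairs",         0.90,       1.40,   1.6,  0.4,
  "cycling",                  0.30,       1.80,   1.5,  0.2,
  "running",                  1.50,       2.50,   2.8,  0.5
)

#' Synthesize an activity-labelled pretraining corpus
#'
#' Generates balanced 1-min rounds of six-channel gyroscope signals for 12
#' activity classes with class-specific spectral signatures: sedentary
#' postures (lying, sitting, ...) have near-zero power, household gestures
#' have wrist-dominant sub-1-Hz motion, and locomotion classes have strong
#' 1.5--2.8 Hz ankle periodicity with harmonics.  The corpus is used only as
#' the transfer-learning pretext task (activity classification).
#'
#' @param n_subjects Number of synthetic subjects the rounds are spread over.
#' @param n_rounds Total number of 1-min rounds (>= 12, one per class).
#' @param fs Sampling rate in Hz.  Corpora generated above 64 Hz are meant to
#'   be brought to 64 Hz with [resample_to_64()] before feature extraction.
#' @param seed Integer seed.
#' @return A tibble with one row per round: `subject`, `round`, `activity`
#'   (factor, 12 levels), `fs`, `X` (list of samples x 6 matrices).
#' @export
#' @examples
#' corp <- synth_activity_corpus(n_rounds = 24, seed = 1)
#' table(corp$activity)
synth_activity_corpus <- function(n_subjects = 9, n_rounds = 455, fs = 64,
                                  seed = 1L) {
  if (n_rounds < nrow(.activity_classes)) {
    stop("need at least one round per class (", nrow(.activity_classes), ")")
  }
  set.seed(seed)
  n <- as.integer(60 * fs)
  t <- (seq_len(n) - 1L) / fs
  cls <- rep_len(seq_len(nrow(.activity_classes)), n_rounds)
  X <- vector("list", n_rounds)
  for (i in seq_len(n_rounds)) {
    p <- .activity_classes[cls[i], ]
    M <- matrix(0, n, 6, dimnames = list(NULL, .gyro_channels))
    for (ch in 1:6) {
      amp <- if (ch <= 3) p$wrist_amp else p$ankle_amp
      amp <- amp * runif(1, 0.7, 1.3)  # round-to-round variability
      sig <- 0.4 * amp * .base_process(n, fs)
      if (p$freq > 0) {
        ph <- runif(1, 0, 2 * pi)
        sig <- sig + amp * sin(2 * pi * p$freq * t + ph) +
          p$harm * amp * sin(2 * pi * 2 * p$freq * t + runif(1, 0, 2 * pi))
      }
      M[, ch] <- sig + rnorm(n, sd = 0.01)
    }
    X[[i]] <- M
  }
  tibble::tibble(
    subject = sprintf("A%02d", rep_len(seq_len(n_subjects), n_rounds)),
    round = seq_len(n_rounds),
    activity = factor(.activity_classes$activity[cls],
                      levels = .activity_classes$activity),
    fs = fs, X = X
  )
}
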