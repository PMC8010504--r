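# Forward simulator: labelled synthetic PD-motion rounds and cohorts.
#
# The signal model is phenomenological, not biomechanical: it realises the two
# symptom families the feature bank targets -- rest tremor as intermittent
# 4-6 Hz oscillation whose amplitude grows with the tremor item subtotal, and
# bradykinesia as an attenuation of the low-frequency base motion (and hence
# of speed and jerk) growing with the bradykinesia item subtotal.

#' Symptom-to-signal profile
#'
#' Parameters mapping UPDRS-III item subtotals to gyroscope signal properties.
#'
#' @param tremor_gain Tremor amplitude per tremor item point (rad/s/point).
#' @param brady_gain Base-motion attenuation per bradykinesia item point
#'   (dimensionless/point): base amplitude is divided by
#'   `1 + brady_gain * subtotal`.
#' @param tremor_freq Tremor frequency in Hz, must lie in \[4, 6\].
#' @param burst_duty Fraction of time the tremor is active, in \[0, 1\].
#' @param burst_mean_s Mean duration of a tremor burst (s).
#' @param base_amp RMS-scale of the low-frequency (< 3 Hz) base motion of an
#'   unimpaired recording (rad/s).
#' @param ankle_tremor_frac Fraction of the tremor amplitude carried by the
#'   ankle channels (the wrist carries the full amplitude).
#' @param noise_sd Additive wide-band sensor noise (rad/s).
#' @return A list of class `symptom_profile`.
#' @export
symptom_profile <- function(tremor_gain = 0.15, brady_gain = 0.1,
                            tremor_freq = 5, burst_duty = 0.6,
                            burst_mean_s = 5, base_amp = 1.0,
                            ankle_tremor_frac = 0.4, noise_sd = 0.02) {
  if (tremor_freq < 4 || tremor_freq > 6) {
    stop("tremor_freq must lie in [4, 6] Hz")
  }
  if (burst_duty < 0 || burst_duty > 1) stop("burst_duty must lie in [0, 1]")
  if (tremor_gain < 0 || brady_gain < 0) stop("gains must be >= 0")
  structure(
    list(tremor_gain = tremor_gain, brady_gain = brady_gain,
         tremor_freq = tremor_freq, burst_duty = burst_duty,
         burst_mean_s = burst_mean_s, base_amp = base_amp,
         ankle_tremor_frac = ankle_tremor_frac, noise_sd = noise_sd),
    class = "symptom_profile"
  )
}

#' @export
print.symptom_profile <- function(x, ...) {
  cat("<symptom_profile> tremor", x$tremor_gain, "rad/s/pt @", x$tremor_freq,
      "Hz, duty", x$burst_duty, "; brady", x$brady_gain, "/pt\n")
  invisible(x)
}

.gyro_channels <- c("wrist_x", "wrist_y", "wrist_z",
                    "ankle_x", "ankle_y", "ankle_z")

# On/off tremor gate: alternating exponentially distributed burst and pause
# durations so that the long-run duty cycle equals `duty`.
.tremor_gate <- function(n, fs, duty, burst_mean_s) {
  if (duty <= 0) return(numeric(n))
  if (duty >= 1) return(rep(1, n))
  pause_mean_s <- burst_mean_s * (1 - duty) / duty
  gate <- numeric(n)
  i <- 1L
  on <- runif(1) < duty  # random initial state
  while (i <= n) {
    len <- max(1L, round(fs * rexp(1, 1 / ifelse(on, burst_mean_s, pause_mean_s))))
    j <- min(n, i + len - 1L)
    if (on) gate[i:j] <- 1
    i <- j + 1L
    on <- !on
  }
  gate
}

# Low-frequency (< 3 Hz) smooth random process of unit RMS.
.base_process <- function(n, fs) {
  lp <- signal::butter(4, min(3 / (fs / 2), 0.95))
  pad <- min(n, 4L * fs)
  x <- signal::filtfilt(lp, rnorm(n + 2L * pad))
  x <- x[(pad + 1L):(pad + n)]
  x / max(sd(x), .Machine$double.eps)
}

#' Synthesize one round of six-channel gyroscope data
#'
#' Generates a `duration_s * fs` by 6 matrix of angular velocities
#' (wrist x/y/z then ankle x/y/z) realising the symptom burden encoded in a
#' UPDRS-III label: a burst-gated sinusoidal tremor component at
#' `profile$tremor_freq` with amplitude `tremor_gain *` tremor subtotal,
#' a smooth sub-3-Hz activities-of-daily-living base motion attenuated by
#' `1 / (1 + brady_gain *` bradykinesia subtotal `)`, and additive sensor
#' noise.  Both sensors sit on the most-affected side and carry the full
#' symptom amplitude (the ankle tremor share is `ankle_tremor_frac`).
#'
#' @param label An [updrs_label()].
#' @param profile A [symptom_profile()].
#' @param duration_s Round duration in seconds (>= 60).
#' @param fs Sampling rate in Hz (>= 32).
#' @param seed Optional integer; when given, the round is generated under a
#'   local RNG state so identical calls are bit-identical.
#' @return A list of class `gyro_round` with elements `X` (samples x 6 matrix),
#'   `fs`, `label`, `subject_id`, `round_id`, `state`.
#' @export
#' @examples
#' r <- synth_round(sample_updrs_label(20), symptom_profile(),
#'                  duration_s = 60, fs = 64, seed = 1)
#' dim(r$X)
synth_round <- function(label, profile = symptom_profile(), duration_s = 240,
                        fs = 64, seed = NULL, subject_id = NA_character_,
                        round_id = NA_integer_, state = NA_character_) {
  if (!inherits(label, "updrs_label")) stop("label must be an updrs_label")
  if (duration_s < 60) stop("duration_s must be >= 60 s")
  if (fs < 32) stop("fs must be >= 32 Hz")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  tremor_amp <- profile$tremor_gain * updrs_subtotal(label, "tremor")
  brady_att <- 1 / (1 + profile$brady_gain * updrs_subtotal(label, "bradykinesia"))

  # fixed per-round axis orientation of the tremor oscillation, unit norm
  w_axis <- abs(rnorm(3)) + 0.2
  w_axis <- w_axis / sqrt(sum(w_axis^2))
  gate <- .tremor_gate(n, fs, profile$burst_duty, profile$burst_mean_s)
  phase <- runif(3, 0, 2 * pi)

  X <- matrix(0, n, 6, dimnames = list(NULL, .gyro_channels))
  for (ch in 1:6) {
    sensor_amp <- if (ch <= 3) 1 else profile$ankle_tremor_frac
    ax <- if (ch <= 3) ch else ch - 3L
    base <- profile$base_amp * brady_att * .base_process(n, fs)
    tremor <- tremor_amp * sensor_amp * w_axis[ax] *
      gate * sin(2 * pi * profile$tremor_freq * t + phase[ax])
    X[, ch] <- base + tremor + rnorm(n, sd = profile$noise_sd)
  }
  structure(
    list(X = X, fs = fs, label = label, subject_id = subject_id,
         round_id = round_id, state = state),
    class = "gyro_round"
  )
}

#' Cohort configuration
#'
#' Describes a synthetic study cohort: per-subject round counts and
#' durations, the sampling rate, and the OFF/ON medication-state UPDRS-III
#' total distributions.
#'
#' @param n_subjects Number of subjects.
#' @param rounds_per_subject Integer vector (length `n_subjects`) of round
#'   counts, each in 2..4.
#' @param round_durations List (length `n_subjects`) of per-round durations in
#'   seconds, each >= 60.
#' @param fs Sampling rate in Hz.
#' @param off_mean,off_sd Mean/sd of the pre-medication (OFF) UPDRS-III total.
#' @param on_mean,on_sd Mean/sd of the post-medication (ON) total.  ON totals
#'   are coupled to the same subject's OFF total (scaled plus residual noise)
#'   so both marginal moments and the within-subject medication drop hold.
#' @param label_jitter_sd Per-round assessment jitter around the state
#'   severity (UPDRS points).
#' @param medication_times Numeric vector of per-subject medication intake
#'   times (s from session start); rounds starting before it are OFF, after
#'   it ON.
#' @param seed Integer seed driving the whole cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, rounds_per_subject, round_durations,
                          fs = 64, off_mean = 29.7, off_sd = 12.3,
                          on_mean = 17.3, on_sd = 8.4, label_jitter_sd = 2,
                          medication_times = NULL, seed = 1L) {
  if (fs <= 0) stop("fs must be > 0")
  rounds_per_subject <- as.integer(rounds_per_subject)
  if (length(rounds_per_subject) != n_subjects ||
      any(!rounds_per_subject %in% 2:4)) {
    stop("rounds_per_subject must give each of the ", n_subjects,
         " subjects 2, 3 or 4 rounds")
  }
  if (length(round_durations) != n_subjects) {
    stop("round_durations must have one entry per subject")
  }
  round_durations <- lapply(seq_len(n_subjects), function(i) {
    d <- rep_len(round_durations[[i]], rounds_per_subject[i])
    if (any(d < 60)) stop("every round duration must be >= 60 s")
    d
  })
  if (is.null(medication_times)) {
    # medication after the first round, separated by 1-h assessment gaps
    medication_times <- vapply(round_durations, function(d) d[1] + 60, 0)
  }
  structure(
    list(n_subjects = n_subjects, rounds_per_subject = rounds_per_subject,
         round_durations = round_durations, fs = fs,
         off_mean = off_mean, off_sd = off_sd,
         on_mean = on_mean, on_sd = on_sd,
         label_jitter_sd = label_jitter_sd,
         medication_times = medication_times, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Published-study cohort configuration
#'
#' The default study layout: 24 subjects and 91 rounds in total -- 15
#' subjects with about 4-min rounds (13 with four rounds, 2 with three) and
#' 9 subjects with 10-min rounds (7 with four, one with three, one with two).
#' OFF totals are drawn from N(29.7, 12.3) and ON totals have marginal
#' moments (17.3, 8.4), clipped to \[0, 108\].
#'
#' @param seed Integer seed.
#' @param duration_scale Multiplier on the round durations (kept at 1 for the
#'   full-fidelity cohort; smaller values give quicker cohorts with the same
#'   label structure for examples).
#' @return A `cohort_config`.
#' @export
cohort_config_study <- function(seed = 1L, duration_scale = 1) {
  rounds <- c(rep(4L, 13), 3L, 3L, rep(4L, 7), 3L, 2L)
  durations <- c(as.list(rep(240 * duration_scale, 15)),
                 as.list(rep(600 * duration_scale, 9)))
  cohort_config(24L, rounds, durations, seed = seed)
}

#' Small smoke-test cohort configuration
#'
#' Six subjects with four 2-min rounds each (two OFF, two ON around the
#' medication intake); used for quick end-to-end runs of the full pipeline.
#'
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
cohort_config_smoke <- function(seed = 1L) {
  cohort_config(6L, rep(4L, 6), as.list(rep(120, 6)),
                medication_times = rep(4000, 6), seed = seed)
}

#' Plan a cohort: subjects, rounds, states and labels (no signals)
#'
#' Draws the label structure of a cohort -- per-subject OFF/ON severities,
#' per-round assessment times and item-level UPDRS-III labels -- without
#' generating any signal, which makes label-distribution checks cheap.
#' Each round is labelled by the assessment nearest to it in time.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per round: `subject`, `round`, `state`
#'   (`"OFF"`/`"ON"`), `t_start`, `duration_s`, `assess_time`, `label`
#'   (list of [updrs_label()]), `updrs_total`.
#' @export
plan_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ratio <- config$on_mean / config$off_mean
  on_resid <- sqrt(max(config$on_sd^2 - (config$off_sd * ratio)^2, 0))
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    s_off <- min(108, max(0, rnorm(1, config$off_mean, config$off_sd)))
    s_on <- min(108, max(0, s_off * ratio + rnorm(1, 0, on_resid)))
    durs <- config$round_durations[[s]]
    med_t <- config$medication_times[s]
    # rounds separated by assessment gaps (hourly exams in the protocol)
    gaps <- 3600 - durs
    t_start <- cumsum(c(0, head(durs + pmax(gaps, 60), -1)))
    for (r in seq_along(durs)) {
      state <- if (t_start[r] < med_t) "OFF" else "ON"
      sev <- if (state == "OFF") s_off else s_on
      target <- min(108, max(0, sev + rnorm(1, 0, config$label_jitter_sd)))
      lab <- sample_updrs_label(target)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = sprintf("S%02d", s), round = r, state = state,
        t_start = t_start[r], duration_s = durs[r],
        assess_time = t_start[r],  # exam held right before each round
        label = list(lab), updrs_total = lab$total
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Synthesize a full labelled cohort
#'
#' Realises a [plan_cohort()] as gyroscope signals: one [synth_round()] per
#' planned round, with a per-subject tremor frequency drawn uniformly from
#' \[4, 6\] Hz and a shared symptom profile.  Identical `config` (including
#' its seed) yields a bit-identical cohort.
#'
#' @param config A [cohort_config()].
#' @param profile A [symptom_profile()]; its `tremor_freq` is overridden per
#'   subject.
#' @return A tibble with the [plan_cohort()] columns plus `fs` and `X`
#'   (list of samples x 6 signal matrices).
#' @export
#' @examples
#' coh <- synth_cohort(cohort_config_smoke(seed = 7))
#' nrow(coh)
synth_cohort <- function(config, profile = symptom_profile()) {
  plan <- plan_cohort(config)
  set.seed(config$seed + 1L)
  subj <- unique(plan$subject)
  freq <- setNames(runif(length(subj), 4, 6), subj)
  seeds <- setNames(sample.int(.Machine$integer.max, nrow(plan)), NULL)
  X <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    prof_i <- profile
    prof_i$tremor_freq <- freq[[plan$subject[i]]]
    X[[i]] <- synth_round(plan$label[[i]], prof_i,
                          duration_s = plan$duration_s[i], fs = config$fs,
                          seed = seeds[i])$X
  }
  out <- plan
  out$fs <- config$fs
  out$X <- X
  attr(out, "cohort_config") <- config
  out
}

#' Synthesize a continuous recording with flagged exam segments
#'
#' Builds one subject's uncut session: rounds of free movement interleaved
#' with short UPDRS-examination segments.  Exam segments are returned as
#' flagged intervals so the preprocessing exclusion rule
#' ([exclude_exam_segments()]) can be exercised; assessments carry the
#' label measured at that exam.
#'
#' @param plan_rows Rows of a [plan_cohort()] for one subject.
#' @param config The [cohort_config()] the plan came from.
#' @param profile A [symptom_profile()].
#' @param exam_duration_s Duration of each exam segment (s).
#' @return A list with `X` (full-session samples x 6 matrix), `fs`,
#'   `exam_intervals` (two-column matrix of half-open \[start, end) times in
#'   seconds), and `assessments` (tibble of `time`, `total`).
#' @export
synth_recording <- function(plan_rows, config, profile = symptom_profile(),
                            exam_duration_s = 60) {
  stopifnot(nrow(plan_rows) >= 1)
  set.seed(config$seed + 2L)
  fs <- config$fs
  pieces <- list(); intervals <- NULL; assess <- NULL
  t_cursor <- 0
  for (i in seq_len(nrow(plan_rows))) {
    lab <- plan_rows$label[[i]]
    exam <- synth_round(lab, profile, duration_s = max(60, exam_duration_s),
                        fs = fs)$X
    intervals <- rbind(intervals,
                       c(t_cursor, t_cursor + nrow(exam) / fs))
    assess <- rbind(assess,
                    tibble::tibble(time = t_cursor, total = lab$total))
    pieces[[length(pieces) + 1L]] <- exam
    t_cursor <- t_cursor + nrow(exam) / fs
    free <- synth_round(lab, profile, duration_s = plan_rows$duration_s[i],
                        fs = fs)$X
    pieces[[length(pieces) + 1L]] <- free
    t_cursor <- t_cursor + nrow(free) / fs
  }
  list(X = do.call(rbind, pieces), fs = fs, exam_intervals = intervals,
       assessments = assess)
}
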