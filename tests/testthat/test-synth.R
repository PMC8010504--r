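# The forward simulator: symptom monotonicity, cohort structure,
# reproducibility and the activity corpus.

band_frac <- function(x, fs, lo, hi) {
  p <- abs(fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sum(p[f >= lo & f <= hi]) / sum(p[f >= 0.1 & f <= fs / 2])
}

test_that("a symptom-free round carries no tremor-band power", {
  lab <- updrs_label(rep(0L, 27))
  r <- synth_round(lab, symptom_profile(noise_sd = 0), 60, 64, seed = 3)
  for (ch in c(1, 4)) {
    expect_lt(band_frac(r$X[, ch], 64, 4, 6), 0.01)
  }
})

test_that("tremor-band power rises with the tremor subtotal (periodogram oracle)", {
  prof <- symptom_profile()
  for (seed in 1:10) {
    items0 <- rep(0L, 27)
    pow <- vapply(c(0L, 2L, 4L, 8L), function(ts) {
      items <- items0
      items[seq_len(ts %/% 2)] <- 2L          # tremor items are 1..7
      r <- synth_round(updrs_label(items), prof, 60, 64, seed = seed)
      band_power(r$X[, 1], 4, 6, 64)
    }, numeric(1))
    expect_true(all(diff(pow) > 0))
  }
})

test_that("mean absolute jerk falls with the bradykinesia subtotal (finite-difference oracle)", {
  prof <- symptom_profile(noise_sd = 0)
  for (seed in 1:10) {
    jerks <- vapply(c(0L, 6L, 12L), function(bs) {
      items <- rep(0L, 27)
      if (bs > 0L) items[8:(7 + bs %/% 2)] <- 2L   # bradykinesia items are 8..19
      r <- synth_round(updrs_label(items), prof, 60, 64, seed = seed)
      mean(abs(diff(r$X[, 1], differences = 2))) * 64^2
    }, numeric(1))
    expect_true(all(diff(jerks) < 0))
  }
})

test_that("study-layout cohort structure: 24 subjects, 91 rounds, 2-4 rounds each", {
  plan <- plan_cohort(cohort_config_study(seed = 7))
  expect_identical(length(unique(plan$subject)), 24L)
  expect_identical(nrow(plan), 91L)
  counts <- table(plan$subject)
  expect_true(all(counts %in% 2:4))
  expect_true(all(plan$duration_s %in% c(240, 600)))
})

test_that("a one-subject two-round config yields exactly two rounds", {
  cc <- cohort_config(1L, 2L, list(60), seed = 1)
  coh <- synth_cohort(cc)
  expect_identical(nrow(coh), 2L)
  expect_identical(nrow(coh$X[[1]]), 60L * 64L)
})

test_that("OFF/ON label means match the generator targets across seeds", {
  offs <- ons <- numeric(25)
  for (s in 1:25) {
    plan <- plan_cohort(cohort_config_study(seed = 500 + s))
    offs[s] <- mean(plan$updrs_total[plan$state == "OFF"])
    ons[s] <- mean(plan$updrs_total[plan$state == "ON"])
  }
  expect_lt(abs(mean(offs) - 29.7), 3)
  expect_lt(abs(mean(ons) - 17.3), 3)
  expect_true(all(offs >= 0 & offs <= 108))
})

test_that("identical config and seed give a bit-identical cohort", {
  c1 <- synth_cohort(cohort_config(3L, rep(2L, 3), as.list(rep(60, 3)), seed = 9))
  c2 <- synth_cohort(cohort_config(3L, rep(2L, 3), as.list(rep(60, 3)), seed = 9))
  expect_identical(c1$X, c2$X)
  expect_identical(c1$updrs_total, c2$updrs_total)
})

test_that("config validation rejects out-of-range structure", {
  expect_error(cohort_config(2L, c(2L, 5L), list(60, 60)), "2, 3 or 4")
  expect_error(cohort_config(1L, 2L, list(30)), ">= 60")
  expect_error(cohort_config(1L, 2L, list(60), fs = 0), "fs")
})

test_that("activity corpus delivers the requested number of balanced rounds", {
  corp <- synth_activity_corpus(n_rounds = 455, seed = 5)
  expect_identical(nrow(corp), 455L)
  expect_identical(nlevels(corp$activity), 12L)
  counts <- table(corp$activity)
  expect_lte(max(counts) - min(counts), 1)
  expect_error(synth_activity_corpus(n_rounds = 5), "one round per class")
})

test_that("sedentary classes have less signal power than locomotion", {
  corp <- synth_activity_corpus(n_rounds = 24, seed = 6)
  pw <- function(i) band_power(corp$X[[i]][, 4], 0.5, 15, 64)
  lying <- which(corp$activity == "lying")
  walking <- which(corp$activity == "walking")
  for (i in lying) for (j in walking) expect_lt(pw(i), pw(j))
})

test_that("a synthesized recording carries flagged exam intervals", {
  cc <- cohort_config(1L, 2L, list(90), seed = 4)
  plan <- plan_cohort(cc)
  rec <- synth_recording(plan, cc)
  expect_identical(nrow(rec$exam_intervals), 2L)
  expect_identical(nrow(rec$assessments), 2L)
  expect_identical(ncol(rec$X), 6L)
})
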