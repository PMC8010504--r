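# Shared fixtures, built lazily and cached for the session so expensive
# artefacts (feature-extracted cohorts, the smoke cross-validation run) are
# computed once across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 2-min 6-channel round with a known label, filtered and feature-ready.
tiny_round <- function(total = 30, seed = 42) {
  set.seed(seed)
  lab <- sample_updrs_label(total)
  synth_round(lab, symptom_profile(), duration_s = 120, fs = 64, seed = seed)
}

# Smoke cohort with features (used by several files).
smoke_cohort_feats <- function() {
  fixture("smoke_cohort", function() {
    coh <- synth_cohort(cohort_config_smoke(seed = 101))
    cohort_features(coh)
  })
}

smoke_corpus_feats <- function() {
  fixture("smoke_corpus", function() {
    activity_features(synth_activity_corpus(n_rounds = 72, seed = 101))
  })
}

# The end-to-end smoke LOOCV over the full model roster; computed once and
# reused by the headline-property and medication-effect checks.
smoke_cv_report <- function() {
  fixture("smoke_cv", function() {
    run_loocv(
      smoke_cohort_feats(),
      models = c("gtb", "dual_tl", "cnn1d", "cnn2d"),
      spec = model_spec("dual_lstm", lstm_layers = 2, n_h = 32),
      control = train_control(dual_epochs = 50L, pretrain_epochs = 12L,
                              stage1_epochs = 8L, stage2_epochs = 30L,
                              stage1_batch_2d = 8L),
      corpus = smoke_corpus_feats(), seed = 101)
  })
}

# Independent scalar implementation of the LSTM recurrence (the model
# equations evaluated element by element, no matrix code shared with the
# package) used as the equation-fidelity oracle.
oracle_lstm_forward <- function(Fv, stack, head) {
  sig <- function(z) 1 / (1 + exp(-z))
  n_h <- length(stack$layers[[1]]$b) / 4
  Tn <- nrow(Fv)
  inputs <- matrix(0, Tn, n_h)
  for (t in seq_len(Tn)) {                          # input projection
    for (j in seq_len(n_h)) {
      inputs[t, j] <- sum(stack$proj$W[j, ] * Fv[t, ]) + stack$proj$b[j]
    }
  }
  for (l in seq_along(stack$layers)) {
    p <- stack$layers[[l]]
    h <- numeric(n_h); cc <- numeric(n_h)
    H <- matrix(0, Tn, n_h)
    for (t in seq_len(Tn)) {
      x <- inputs[t, ]
      hn <- numeric(n_h); cn <- numeric(n_h)
      for (j in seq_len(n_h)) {
        gi <- sig(sum(p$Wx[j, ] * x) + sum(p$Wh[j, ] * h) + p$b[j])
        gg <- tanh(sum(p$Wx[n_h + j, ] * x) + sum(p$Wh[n_h + j, ] * h) +
                     p$b[n_h + j])
        gf <- sig(sum(p$Wx[2 * n_h + j, ] * x) + sum(p$Wh[2 * n_h + j, ] * h) +
                    p$b[2 * n_h + j])
        go <- sig(sum(p$Wx[3 * n_h + j, ] * x) + sum(p$Wh[3 * n_h + j, ] * h) +
                    p$b[3 * n_h + j])
        cn[j] <- gf * cc[j] + gi * gg
        hn[j] <- go * tanh(cn[j])
      }
      h <- hn; cc <- cn
      H[t, ] <- h
    }
    inputs <- H
  }
  sum(head$W[1, ] * inputs[Tn, ]) + head$b[1]       # linear readout of the last hidden state
}

# Brute-force O(n^2) sample entropy (double loop, Chebyshev, no self-match).
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (j <= i) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(log((n - m) * (n - m - 1)))
  -log(A / B)
}

# Direct-sum autocorrelation (demeaned, normalized at lag 0).
oracle_autocorr <- function(x, max_lag) {
  x <- x - mean(x)
  v <- sum(x^2)
  vapply(0:max_lag, function(k) {
    sum(x[1:(length(x) - k)] * x[(1 + k):length(x)]) / v
  }, numeric(1))
}
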