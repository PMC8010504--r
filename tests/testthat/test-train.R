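# Training procedures: augmentation, model selection, two-stage and
# transfer contracts, and the evaluation statistics.

test_that("random-start augmentation returns uniform suffixes", {
  M <- matrix(rnorm(96), 48, 2)
  expect_identical(random_start_augment(M, start = 0), M)
  expect_identical(nrow(random_start_augment(M, start = 10)), 38L)
  expect_identical(random_start_augment(M[1, , drop = FALSE]),
                   M[1, , drop = FALSE])
  set.seed(31)
  len <- 8
  starts <- replicate(4000, nrow(random_start_augment(M[1:len, ])))
  freq <- table(factor(len - starts, levels = 0:(len - 1))) / 4000
  se <- sqrt((1 / len) * (1 - 1 / len) / 4000)
  expect_true(all(abs(freq - 1 / len) < 3.5 * se + 0.01))
})

test_that("pearson and MAE match hand-computed examples", {
  expect_equal(unname(pearson_mae(c(0, 1, 2), c(0, 1, 2))), c(1, 0))
  pm <- pearson_mae(c(0, 1, 2), c(0, 2, 1))
  expect_equal(unname(pm), c(0.5, 2 / 3))
  expect_equal(unname(pearson_mae(c(1, 2, 3), c(2, 3, 4))), c(1, 1))
  expect_warning(pm0 <- pearson_mae(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(pm0["rho"]))
  expect_error(pearson_mae(1:3, 1:4), "equal length")
})

test_that("medication-effect test follows the degenerate conventions", {
  x <- c(30, 28, 35, 25)
  same <- medication_effect_test(x, x)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_false(same$degenerate)

  deg <- medication_effect_test(c(30, 28, 35, 25), c(20, 18, 25, 15))
  expect_true(deg$degenerate)
  expect_equal(deg$mean_before - deg$mean_after, 10)

  set.seed(32)
  rej <- mean(replicate(300, {
    off <- rnorm(24, 30, 8)
    on <- off - rnorm(24, 10, 4)
    medication_effect_test(off, on)$p < 0.001
  }))
  expect_gt(rej, 0.95)
})

test_that("fold plans never leak the held-out subject", {
  coh <- smoke_cohort_feats()
  folds <- plan_folds(coh, seed = 5)
  expect_identical(nrow(folds), length(unique(coh$subject)))
  for (k in seq_len(nrow(folds))) {
    te <- folds$test_rows[[k]]
    expect_length(intersect(te, folds$train_rows[[k]]), 0L)
    expect_length(intersect(te, folds$val_rows[[k]]), 0L)
    expect_setequal(coh$subject[te], folds$test_subject[k])
  }
})

test_that("dual-LSTM training selects the best-validation epoch and descends", {
  coh <- smoke_cohort_feats()
  st_S <- updrsens:::.stack_stats(coh$S)
  st_L <- updrsens:::.stack_stats(coh$L)
  mkset <- function(rows) list(
    S = lapply(coh$S[rows], normalize, stats = st_S),
    L = lapply(coh$L[rows], normalize, stats = st_L),
    y = scale(coh$updrs_total)[rows, 1])
  fit <- train_dual_lstm(mkset(1:12), mkset(13:18),
                         model_spec("dual_lstm", lstm_layers = 1, n_h = 16),
                         epochs = 15, seed = 7)
  expect_identical(fit$best_epoch, which.max(fit$history))
  expect_true(all(is.finite(fit$history)))
})

test_that("two-stage training freezes the CNN and reuses its embeddings exactly", {
  coh <- smoke_cohort_feats()
  st_sig <- updrsens:::.stack_stats(coh$Xf)
  wins <- lapply(seq_len(nrow(coh)), function(i) {
    segment_windows(normalize(coh$Xf[[i]], st_sig), 64)$short
  })
  yz <- scale(coh$updrs_total)[, 1]
  spec <- model_spec("cnn1d_lstm", lstm_layers = 1, n_h = 16)
  cnn <- build_cnn1d(spec)
  tr <- list(wins = wins[1:10], y = yz[1:10])
  va <- list(wins = wins[11:14], y = yz[11:14])
  fit <- two_stage_train(tr, va, cnn, spec, stage1_epochs = 3,
                         stage2_epochs = 12, seed = 9)
  # frozen-weights contract: embeddings recomputed from the saved CNN are
  # bit-identical between calls
  e1 <- updrsens:::cnn_embed(fit$cnn, fit$params$cnn, wins[[15]])
  e2 <- updrsens:::cnn_embed(fit$cnn, fit$params$cnn, wins[[15]])
  expect_identical(e1, e2)
  expect_identical(unname(fit$best_epochs["stage2"]),
                   which.max(fit$stage2_history))
  # smoke descent: late training loss below the first epoch's
  expect_lt(fit$stage2_loss[12], fit$stage2_loss[1])
  expect_error(two_stage_train(tr, list(wins = list(), y = numeric()),
                               cnn, spec), "validation")
  # determinism: same seed, same fit
  fit2 <- two_stage_train(tr, va, cnn, spec, stage1_epochs = 3,
                          stage2_epochs = 12, seed = 9)
  expect_identical(fit$params, fit2$params)
})

test_that("activity pretraining beats chance and freezing is respected", {
  corp <- smoke_corpus_feats()
  st_S <- updrsens:::.stack_stats(corp$S)
  corpus <- list(S = lapply(corp$S, normalize, stats = st_S),
                 class = as.integer(corp$activity))
  spec <- model_spec("dual_lstm", lstm_layers = 2, n_h = 16)
  pre <- pretrain_activity_lstm(corpus, spec, epochs = 12, seed = 3)
  expect_gt(pre$val_accuracy, 1 / 12)

  coh <- smoke_cohort_feats()
  st_L <- updrsens:::.stack_stats(coh$L)
  mkset <- function(rows) list(
    S = lapply(coh$S[rows], normalize, stats = st_S),
    L = lapply(coh$L[rows], normalize, stats = st_L),
    y = scale(coh$updrs_total)[rows, 1])
  fit <- transfer_pretrain_finetune(corpus, mkset(1:12), mkset(13:18), spec,
                                    pretrain_epochs = 12, epochs = 10, seed = 3)
  # frozen lower layer identical to the pretrained weights after fine-tuning
  expect_identical(fit$params$s$layers[[1]], fit$pretrained$stack$layers[[1]])
  # the fine-tuned last layer moved
  expect_false(identical(fit$params$s$layers[[2]],
                         fit$pretrained$stack$layers[[2]]))
  bad <- corpus
  bad$S <- lapply(bad$S, function(m) m[, 1:20])
  expect_error(transfer_pretrain_finetune(bad, mkset(1:12), mkset(13:18),
                                          spec), "dimension mismatch")
})
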