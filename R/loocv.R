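# Leave-one-subject-out cross-validation harness, evaluation metrics and
# the CV report container.

#' Pearson correlation and mean absolute error
#'
#' @param y,yhat Equal-length numeric vectors of reference and estimated
#'   scores.
#' @return Named vector `(rho, mae)`; `rho` is `NA` (with a warning) when
#'   either input has zero variance.
#' @export
#' @examples
#' pearson_mae(c(0, 1, 2), c(0, 2, 1))  # rho 0.5, mae 2/3
pearson_mae <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0L) {
    stop("y and yhat must be nonempty and of equal length")
  }
  mae <- mean(abs(y - yhat))
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    warning("zero variance; Pearson correlation undefined")
    return(c(rho = NA_real_, mae = mae))
  }
  c(rho = stats::cor(y, yhat), mae = mae)
}

#' Paired medication-effect test
#'
#' Two-sided paired t-test of per-subject scores before versus (about 1 h)
#' after medication intake, plus the group means for a box-plot style
#' summary.  Identical pairs return the `t = 0, p = 1` convention; a
#' zero-variance nonzero difference is flagged degenerate.
#'
#' @param before,after Equal-length per-subject score vectors.
#' @return A list with `t`, `p`, `mean_before`, `mean_after`, `n`,
#'   `degenerate`.
#' @export
medication_effect_test <- function(before, after) {
  if (length(before) != length(after) || length(before) < 3L) {
    stop("need paired scores for at least 3 subjects")
  }
  d <- before - after
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, mean_before = mean(before),
                  mean_after = mean(after), n = length(d), degenerate = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_before = mean(before),
                mean_after = mean(after), n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(before, after, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_before = mean(before), mean_after = mean(after),
       n = length(d), degenerate = FALSE)
}

#' Plan leave-one-subject-out folds
#'
#' One fold per subject: that subject's rounds are the test set, a random
#' 20% of the remaining rounds are the inner validation set, and the rest
#' train.  The held-out subject's rounds never enter training, validation
#' or normalization.
#'
#' @param cohort A cohort tibble (`subject`, `round` columns).
#' @param val_frac Inner validation fraction of the training rounds.
#' @param seed Integer seed.
#' @return A tibble with one row per fold: `fold`, `test_subject`,
#'   `val_rows`, `train_rows` (row indices into `cohort`).
#' @export
plan_folds <- function(cohort, val_frac = 0.2, seed = 1L) {
  set.seed(seed)
  subjects <- unique(cohort$subject)
  purrr::map_dfr(seq_along(subjects), function(k) {
    test_rows <- which(cohort$subject == subjects[k])
    rest <- setdiff(seq_len(nrow(cohort)), test_rows)
    n_val <- max(2L, round(val_frac * length(rest)))
    val_rows <- sort(sample(rest, n_val))
    tibble::tibble(fold = k, test_subject = subjects[k],
                   test_rows = list(test_rows), val_rows = list(val_rows),
                   train_rows = list(setdiff(rest, val_rows)))
  })
}

# Per-fold normalization helpers -------------------------------------------

.stack_stats <- function(mats) norm_stats(do.call(rbind, mats))

# Channel-wise stats of a list of spectrogram tensors.
.spg_stats <- function(spgs) {
  acc_n <- 0; acc_s <- numeric(6); acc_q <- numeric(6)
  for (s in spgs) {
    m <- matrix(s, ncol = 6)
    acc_n <- acc_n + nrow(m)
    acc_s <- acc_s + colSums(m)
    acc_q <- acc_q + colSums(m^2)
  }
  mu <- acc_s / acc_n
  list(mean = mu, sd = sqrt(pmax(acc_q / acc_n - mu^2, 0)))
}

.norm_spg <- function(spg, st) {
  m <- normalize(matrix(spg, ncol = 6), st)
  array(m, dim = dim(spg))
}

# Feature/window/label views of selected cohort rows under train stats.
.fold_view <- function(cohort, rows, st) {
  list(
    S = lapply(cohort$S[rows], normalize, stats = st$S),
    L = lapply(cohort$L[rows], normalize, stats = st$L),
    wins = lapply(rows, function(i) {
      ws <- segment_windows(normalize(cohort$Xf[[i]], st$sig), cohort$fs[i])
      ws$short
    }),
    spg = if (!is.null(st$spg)) lapply(rows, function(i) {
      lapply(cohort$SPG[[i]], .norm_spg, st = st$spg)
    }),
    y = (cohort$updrs_total[rows] - st$y$mean) / st$y$sd
  )
}

#' Training-schedule control
#'
#' Bundles the training schedule used inside [run_loocv()].  The defaults
#' are the full-fidelity settings (200 epochs, Adam, learning rate 1e-3,
#' mini-batch 2); pass smaller values for desk-scale runs.
#'
#' @param dual_epochs,pretrain_epochs Dual-channel LSTM fine-tune and
#'   activity-pretraining epochs.
#' @param stage1_epochs,stage2_epochs CNN-LSTM two-stage schedule.
#' @param lr Adam learning rate.
#' @param batch Rounds per mini-batch.
#' @param stage1_batch_1d,stage1_batch_2d Windows per stage-1 mini-batch.
#' @param stage1_max_windows Training windows sampled per stage-1 epoch.
#' @param gtb_search Hyperparameter grid for the tree-boosting baseline.
#' @return A list of class `train_control`.
#' @export
train_control <- function(dual_epochs = 200L, pretrain_epochs = 20L,
                          stage1_epochs = 200L, stage2_epochs = 200L,
                          lr = 1e-3, batch = 2L, stage1_batch_1d = 16L,
                          stage1_batch_2d = 4L, stage1_max_windows = 512L,
                          gtb_search = gtb_grid(trees = c(50, 110, 170),
                                                depth = c(3, 5),
                                                colsample = c(0.3, 0.5))) {
  structure(as.list(environment()), class = "train_control")
}

#' Leave-one-subject-out evaluation of the model roster
#'
#' For every fold: computes normalization statistics from the training
#' rounds only, trains the requested models (tree boosting; dual-channel
#' LSTM with or without transfer pretraining; 1D and 2D CNN-LSTM with
#' two-stage training), estimates the held-out subject's rounds, and pools
#' all test estimates.  Reports Pearson correlation and MAE per single
#' model and for the ensembles of two or three deep models, plus the
#' paired medication-effect test on per-subject OFF/ON ensemble estimates.
#'
#' @param cohort A cohort with feature columns (see [cohort_features()]).
#' @param models Character subset of
#'   `c("gtb", "dual_tl", "dual", "cnn1d", "cnn2d")`.
#' @param spec A [model_spec()] providing the shared LSTM width/depth.
#' @param control A [train_control()].
#' @param corpus Activity corpus tibble ([synth_activity_corpus()]) with
#'   features extracted; required when `"dual_tl"` is requested.
#' @param seed Integer master seed; per-fold seeds derive from it.
#' @return A `cv_report`: list with `predictions` (per-round tibble),
#'   `metrics` (per-model tibble), `med_test`, `folds`.
#' @export
run_loocv <- function(cohort, models = c("gtb", "dual_tl", "cnn1d", "cnn2d"),
                      spec = model_spec("dual_lstm", lstm_layers = 2, n_h = 64),
                      control = train_control(), corpus = NULL, seed = 1L) {
  models <- match.arg(models, c("gtb", "dual_tl", "dual", "cnn1d", "cnn2d"),
                      several.ok = TRUE)
  if (length(unique(cohort$subject)) < 3L) stop("need at least 3 subjects")
  if ("dual_tl" %in% models && is.null(corpus)) {
    stop("transfer learning needs an activity corpus (see synth_activity_corpus)")
  }
  corp <- NULL
  if (!is.null(corpus)) {
    corp <- list(S = corpus$S, class = as.integer(corpus$activity))
  }
  folds <- plan_folds(cohort, seed = seed)
  preds <- list()
  for (k in seq_len(nrow(folds))) {
    fseed <- seed + 1000L * k
    tr <- folds$train_rows[[k]]; va <- folds$val_rows[[k]]
    te <- folds$test_rows[[k]]
    st <- list(
      S = .stack_stats(cohort$S[tr]),
      L = .stack_stats(cohort$L[tr]),
      sig = .stack_stats(cohort$Xf[tr]),
      spg = if (any(c("cnn2d") %in% models)) .spg_stats(
        unlist(cohort$SPG[tr], recursive = FALSE)) else NULL,
      y = list(mean = mean(cohort$updrs_total[tr]),
               sd = max(stats::sd(cohort$updrs_total[tr]), 1e-8))
    )
    vtr <- .fold_view(cohort, tr, st)
    vva <- .fold_view(cohort, va, st)
    vte <- .fold_view(cohort, te, st)
    unz <- function(yz) yz * st$y$sd + st$y$mean
    out <- tibble::tibble(subject = cohort$subject[te],
                          round = cohort$round[te],
                          state = cohort$state[te],
                          y = cohort$updrs_total[te])

    if ("gtb" %in% models) {
      gtr <- list(S = vtr$S, L = vtr$L, y = vtr$y)
      out$gtb <- unz(gtb_fit_predict(
        gtr, list(S = vte$S, L = vte$L),
        val = list(S = vva$S, L = vva$L, y = vva$y),
        grid = control$gtb_search))
    }
    if ("dual" %in% models) {
      fit <- train_dual_lstm(vtr, vva, spec, epochs = control$dual_epochs,
                             lr = control$lr, batch = control$batch,
                             seed = fseed)
      out$dual <- unz(vapply(seq_along(vte$y), function(i) {
        dual_channel_forward(vte$S[[i]], vte$L[[i]], fit$params)
      }, numeric(1)))
    }
    if ("dual_tl" %in% models) {
      corp_n <- list(S = lapply(corp$S, normalize, stats = st$S),
                     class = corp$class)
      fit <- transfer_pretrain_finetune(
        corp_n, vtr, vva, spec, pretrain_epochs = control$pretrain_epochs,
        epochs = control$dual_epochs, lr = control$lr, seed = fseed)
      out$dual_tl <- unz(vapply(seq_along(vte$y), function(i) {
        dual_channel_forward(vte$S[[i]], vte$L[[i]], fit$params)
      }, numeric(1)))
    }
    if ("cnn1d" %in% models) {
      cnn <- build_cnn1d(model_spec("cnn1d_lstm", spec$lstm_layers, spec$n_h))
      fit <- two_stage_train(vtr, vva, cnn,
                             model_spec("cnn1d_lstm", spec$lstm_layers, spec$n_h),
                             stage1_epochs = control$stage1_epochs,
                             stage2_epochs = control$stage2_epochs,
                             lr = control$lr,
                             stage1_batch = control$stage1_batch_1d,
                             stage1_max_windows = control$stage1_max_windows,
                             seed = fseed + 1L)
      out$cnn1d <- unz(vapply(seq_along(vte$y), function(i) {
        cnn_lstm_forward(list(cnn = fit$cnn, params = fit$params),
                         vte$wins[[i]])
      }, numeric(1)))
    }
    if ("cnn2d" %in% models) {
      dims <- dim(cohort$SPG[[1]][[1]])[1:2]
      cnn <- build_cnn2d(model_spec("cnn2d_lstm", spec$lstm_layers, spec$n_h),
                         dims = dims)
      tr2 <- list(wins = vtr$spg, y = vtr$y)
      va2 <- list(wins = vva$spg, y = vva$y)
      fit <- two_stage_train(tr2, va2, cnn,
                             model_spec("cnn2d_lstm", spec$lstm_layers, spec$n_h),
                             stage1_epochs = control$stage1_epochs,
                             stage2_epochs = control$stage2_epochs,
                             lr = control$lr,
                             stage1_batch = control$stage1_batch_2d,
                             stage1_max_windows = control$stage1_max_windows,
                             seed = fseed + 2L)
      out$cnn2d <- unz(vapply(seq_along(vte$y), function(i) {
        cnn_lstm_forward(list(cnn = fit$cnn, params = fit$params),
                         vte$spg[[i]])
      }, numeric(1)))
    }
    preds[[k]] <- out
  }
  predictions <- dplyr::bind_rows(preds)

  deep <- intersect(c("dual_tl", "cnn1d", "cnn2d"), names(predictions))
  pairs <- list(ens_tl_1d = c("dual_tl", "cnn1d"),
                ens_tl_2d = c("dual_tl", "cnn2d"),
                ens_1d_2d = c("cnn1d", "cnn2d"))
  for (nm in names(pairs)) {
    if (all(pairs[[nm]] %in% deep)) {
      predictions[[nm]] <- rowMeans(predictions[, pairs[[nm]]])
    }
  }
  if (length(deep) == 3L) {
    predictions$ensemble <- vapply(seq_len(nrow(predictions)), function(i) {
      ensemble_average(c(predictions$dual_tl[i], predictions$cnn1d[i],
                         predictions$cnn2d[i]))
    }, numeric(1))
  }

  model_cols <- setdiff(names(predictions),
                        c("subject", "round", "state", "y"))
  metrics <- purrr::map_dfr(model_cols, function(m) {
    pm <- suppressWarnings(pearson_mae(predictions$y, predictions[[m]]))
    tibble::tibble(model = m, rho = pm["rho"], mae = pm["mae"])
  })

  med <- NULL
  ens_col <- if ("ensemble" %in% model_cols) "ensemble" else model_cols[1]
  bysub <- predictions |>
    dplyr::group_by(.data$subject, .data$state) |>
    dplyr::summarise(est = mean(.data[[ens_col]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "state", values_from = "est")
  if (all(c("OFF", "ON") %in% names(bysub))) {
    ok <- stats::complete.cases(bysub[, c("OFF", "ON")])
    if (sum(ok) >= 3L) med <- medication_effect_test(bysub$OFF[ok], bysub$ON[ok])
  }

  structure(list(predictions = predictions, metrics = metrics,
                 med_test = med, folds = folds, seed = seed,
                 models = model_cols),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", nrow(x$folds), "folds,", nrow(x$predictions),
      "pooled test rounds\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  if (!is.null(x$med_test)) {
    cat(sprintf("medication effect: t = %.2f, p = %.3g (means %.1f -> %.1f)\n",
                x$med_test$t, x$med_test$p, x$med_test$mean_before,
                x$med_test$mean_after))
  }
  invisible(x)
}

#' Tidy per-model metrics of a CV report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A tibble with `model`, `rho`, `mae`.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$metrics

#' One-row summary of a CV report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A tibble with the headline (ensemble, or first model) `rho`,
#'   `mae`, counts and the medication-effect p value.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  ens <- if ("ensemble" %in% x$metrics$model) "ensemble" else x$metrics$model[1]
  row <- x$metrics[x$metrics$model == ens, ]
  tibble::tibble(model = ens, rho = row$rho, mae = row$mae,
                 n_rounds = nrow(x$predictions),
                 n_subjects = nrow(x$folds),
                 med_p = if (is.null(x$med_test)) NA_real_ else x$med_test$p)
}

#' Scatter of estimated versus reference UPDRS-III scores
#'
#' @param object A `cv_report`.
#' @param model Which prediction column to plot (default the ensemble).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, model = NULL, ...) {
  if (is.null(model)) {
    model <- if ("ensemble" %in% object$models) "ensemble" else object$models[1]
  }
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data[[model]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Clinical UPDRS-III", y = paste("Estimated:", model),
                  title = "Estimated vs. clinical UPDRS-III (pooled LOOCV)") +
    ggplot2::coord_equal()
}

#' Per-subject time course of estimated and reference scores
#'
#' @param report A `cv_report`.
#' @param model Prediction column (default ensemble).
#' @return A ggplot object faceted by subject.
#' @export
plot_timecourse <- function(report, model = NULL) {
  if (is.null(model)) {
    model <- if ("ensemble" %in% report$models) "ensemble" else report$models[1]
  }
  df <- tidyr::pivot_longer(report$predictions,
                            cols = tidyr::all_of(c("y", model)),
                            names_to = "series", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$score,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~subject) +
    ggplot2::labs(x = "Round", y = "UPDRS-III", colour = NULL)
}
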