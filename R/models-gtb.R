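# Gradient Tree Boosting baseline: additive regression-tree ensemble
# (second-order objective, via xgboost) on per-5-s-window vectors that
# concatenate the short-term features with the window's repeated long-term
# features; round estimates average the window estimates.

#' Combined per-window feature matrix for tree boosting
#'
#' Repeats each 1-min long-term feature vector over its 12 constituent 5-s
#' windows and concatenates it with the short-term vectors, yielding
#' `n_short` x 58 (= 26 + 32).
#'
#' @param S `n_short` x 26 short-term feature matrix.
#' @param L `n_long` x 32 long-term feature matrix.
#' @return `n_short` x 58 matrix.
#' @export
gtb_windows <- function(S, L) {
  if (nrow(S) != 12L * nrow(L)) {
    stop("need n_short == 12 * n_long, got ", nrow(S), " and ", nrow(L))
  }
  cbind(S, L[rep(seq_len(nrow(L)), each = 12L), , drop = FALSE])
}

#' Default Gradient-Tree-Boosting search grid
#'
#' Trees 10--200 step 20, depth 3--10 step 2, feature fraction per tree
#' 10--50% step 10%, learning rate 0.1.
#'
#' @param trees,depth,colsample Optional overrides (kept within the ranges
#'   above).
#' @return A data frame of grid points.
#' @export
gtb_grid <- function(trees = seq(10, 200, by = 20),
                     depth = seq(3, 10, by = 2),
                     colsample = seq(0.1, 0.5, by = 0.1)) {
  expand.grid(trees = trees, depth = depth, colsample = colsample)
}

#' Fit the tree-boosting baseline and predict held-out rounds
#'
#' Fits an additive regression-tree ensemble (learning rate 0.1,
#' second-order objective) on the pooled training windows, selecting the
#' grid point with the best validation-round Pearson correlation, then
#' estimates each test round as the mean of its window estimates.
#'
#' @param train A tibble/list with elements `S`, `L` (lists of feature
#'   matrices) and `y` (round labels); pooled into window rows.
#' @param test Same structure; one estimate per round is returned.
#' @param val Optional validation set (same structure) for grid selection;
#'   when NULL the first grid point is used.
#' @param grid Data frame from [gtb_grid()]; must be nonempty.
#' @param eta Learning rate, default 0.1.
#' @return Numeric vector of per-round estimates for `test`.
#' @export
gtb_fit_predict <- function(train, test, val = NULL, grid = gtb_grid(),
                            eta = 0.1) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty hyperparameter grid")
  Xtr <- do.call(rbind, purrr::map2(train$S, train$L, gtb_windows))
  ytr <- rep(train$y, vapply(train$S, nrow, integer(1)))
  dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1)
  fit_one <- function(g) {
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = eta,
                    max_depth = g$depth, colsample_bytree = g$colsample,
                    nthread = 1),
      data = dtr, nrounds = g$trees, verbose = 0)
  }
  predict_rounds <- function(fit, set) {
    vapply(seq_along(set$S), function(i) {
      mean(predict(fit, xgboost::xgb.DMatrix(
        gtb_windows(set$S[[i]], set$L[[i]]), nthread = 1)))
    }, numeric(1))
  }
  best <- NULL
  if (!is.null(val) && nrow(grid) > 1L && length(val$y) >= 3L &&
      stats::sd(val$y) > 0) {
    score <- -Inf
    for (gi in seq_len(nrow(grid))) {
      fit <- fit_one(grid[gi, ])
      rho <- suppressWarnings(stats::cor(val$y, predict_rounds(fit, val)))
      if (is.finite(rho) && rho > score) {
        score <- rho; best <- fit
      }
    }
  }
  if (is.null(best)) best <- fit_one(grid[1, ])
  predict_rounds(best, test)
}
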