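# Gradient-boosted-tree ranking: logistic-loss XGBoost tuned by k-fold
# cross-validated classification error, features ranked by fractional
# total gain.

#' Tune and fit a gradient-boosted classifier
#'
#' Logistic-loss boosting over a (max_depth, learning-rate) grid; each grid
#' point is scored by k-fold cross-validated binary classification error
#' with the number of rounds chosen by early stopping on the folds, and the
#' winner is refit on all data at its early-stopped round count. Ties break
#' toward the shallower, slower-learning (more regularized) setting.
#' Single-threaded and seeded, so reruns are identical.
#'
#' @param m scaled-stage [abundance_matrix()] (any numeric matrix works).
#' @param y binary outcome vector (0/1).
#' @param param_grid data.frame with columns `max_depth` and `eta`;
#'   default `max_depth` 2/4/6 by `eta` 0.05/0.1/0.3.
#' @param folds cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment and tree construction.
#' @param nrounds_max maximum boosting rounds (default 200).
#' @param early_stopping rounds without improvement before stopping
#'   (default 20).
#' @return list of class `boosted_model`: the booster, chosen parameters,
#'   `nrounds`, `cv_error`, `seed`, and the tuning trace.
#' @export
tune_and_fit_xgb <- function(m, y,
                             param_grid = expand.grid(max_depth = c(2, 4, 6),
                                                      eta = c(0.05, 0.1, 0.3)),
                             folds = 5, seed = 1L, nrounds_max = 200,
                             early_stopping = 20) {
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  if (!nrow(param_grid)) stop("empty tuning grid")
  X <- unclass(m)
  if (is.null(colnames(X))) stop("feature columns must be named")
  dm <- xgboost::xgb.DMatrix(X, label = y)
  grid <- param_grid
  grid$cv_error <- NA_real_
  grid$best_iter <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    set.seed(seed)
    cv <- xgboost::xgb.cv(params = list(objective = "binary:logistic",
                                        max_depth = grid$max_depth[i],
                                        eta = grid$eta[i],
                                        eval_metric = "error",
                                        nthread = 1, seed = seed),
                          data = dm, nrounds = nrounds_max, nfold = folds,
                          early_stopping_rounds = early_stopping,
                          verbose = FALSE)
    bi <- cv$early_stop$best_iteration
    grid$best_iter[i] <- bi
    grid$cv_error[i] <- cv$evaluation_log$test_error_mean[bi]
  }
  cand <- grid[grid$cv_error == min(grid$cv_error), , drop = FALSE]
  cand <- cand[order(cand$max_depth, cand$eta), , drop = FALSE]
  best <- cand[1, ]
  set.seed(seed)
  booster <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = best$max_depth,
                                              eta = best$eta,
                                              nthread = 1, seed = seed),
                                data = dm, nrounds = best$best_iter)
  structure(list(booster = booster, max_depth = best$max_depth,
                 eta = best$eta, nrounds = best$best_iter,
                 cv_error = best$cv_error, seed = seed, tuning = grid,
                 feature_ids = colnames(X)),
            class = "boosted_model")
}

#' @export
print.boosted_model <- function(x, ...) {
  cat(sprintf("boosted_model: %d rounds, max_depth = %d, eta = %.2f, CV error = %.3f\n",
              x$nrounds, x$max_depth, x$eta, x$cv_error))
  invisible(x)
}

#' Rank features by fractional total gain
#'
#' Each feature's score is its share of the total training-loss reduction
#' attributable to its splits (gains are normalized to sum to 1 over used
#' features). Features never used by any tree are imputed at rank
#' `n_total`; ties break by feature id.
#'
#' @param model a `boosted_model` from [tune_and_fit_xgb()], or a named
#'   nonnegative per-feature total-gain vector.
#' @param n_total total feature count used as the imputed rank.
#' @return a [method_ranking()] with method `"xgboost"`; `score` is the
#'   gain fraction.
#' @export
rank_xgb_gain <- function(model, n_total = NULL) {
  if (inherits(model, "boosted_model")) {
    imp <- xgboost::xgb.importance(model = model$booster)
    if (is.null(imp) || !nrow(imp)) stop("model contains no splits")
    ids <- model$feature_ids
    gain <- setNames(numeric(length(ids)), ids)
    gain[imp$Feature] <- imp$Gain
  } else {
    gain <- model
    if (is.null(names(gain))) stop("gain vector must be named by feature id")
    if (any(gain < 0)) stop("gains must be nonnegative")
    ids <- names(gain)
  }
  if (sum(gain) == 0) stop("model contains no splits")
  if (is.null(n_total)) n_total <- length(ids)
  score <- gain / sum(gain)
  rank_from_keys("xgboost", ids, score, keys = list(-score, ids),
                 selected = score > 0, n_total = n_total)
}
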