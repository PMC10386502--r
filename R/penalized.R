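# Penalized logistic ranking: LASSO and elastic net via glmnet, with
# age/sex entering as unpenalized covariates (mirroring the univariate
# adjustment) and excluded from the ranking.

# internal: stratified, seeded fold assignment
stratified_folds <- function(y, folds, seed) {
  if (folds < 2) stop("`folds` must be >= 2")
  if (length(y) < folds) stop("fewer samples than folds")
  set.seed(seed)
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

# internal: shared worker for both penalized fits
penalized_cv_one_alpha <- function(X, y, alpha, foldid, penalty.factor,
                                   nlambda, lambda.min.ratio) {
  glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                    foldid = foldid, penalty.factor = penalty.factor,
                    standardize = FALSE, nlambda = nlambda,
                    lambda.min.ratio = lambda.min.ratio,
                    type.measure = "deviance")
}

penalized_fit <- function(m, meta, alpha_grid, folds, seed, nlambda,
                          lambda.min.ratio, adjust_covariates) {
  if (!abundance_stage(m) == "scaled")
    stop("penalized fits expect a scaled abundance matrix")
  meta <- validate_metadata(meta, m)
  y <- meta$outcome
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  p <- ncol(m)
  if (adjust_covariates) {
    X <- cbind(unclass(m), age = meta$age,
               female = as.numeric(meta$sex == "female"))
    pf <- c(rep(1, p), 0, 0)
  } else {
    X <- unclass(m)
    pf <- rep(1, p)
  }
  foldid <- stratified_folds(y, folds, seed)
  fits <- lapply(alpha_grid, function(a)
    penalized_cv_one_alpha(X, y, a, foldid, pf, nlambda, lambda.min.ratio))
  cvmin <- vapply(fits, function(f) min(f$cvm), 0)
  # ties broken toward the larger (sparser) alpha
  best <- which(cvmin == min(cvmin))
  best <- best[which.max(alpha_grid[best])]
  fit <- fits[[best]]
  co <- as.numeric(coef(fit, s = "lambda.min"))[1 + seq_len(p)]
  names(co) <- colnames(m)
  cv <- structure(list(alpha_grid = alpha_grid,
                       chosen_alpha = alpha_grid[best],
                       lambda_grid = fit$lambda,
                       cv_error = fit$cvm,
                       chosen_lambda = fit$lambda.min,
                       cv_error_by_alpha = cvmin,
                       fold_assignment_seed = seed,
                       nonzero_path = fit$nzero,
                       adjust_covariates = adjust_covariates),
                  class = "cv_penalized")
  list(coefficients = co, cv = cv, fit = fit)
}

#' LASSO logistic regression with cross-validated lambda
#'
#' L1-penalized logistic fit over a descending lambda grid (100 log-spaced
#' points from the analytic lambda-max down to 1e-3 of it), choosing the
#' lambda that minimizes the 10-fold cross-validated binomial deviance.
#' Folds are stratified by outcome and seeded. Age and sex enter as
#' unpenalized covariates by default and never appear in the ranking.
#'
#' @param m scaled-stage [abundance_matrix()].
#' @param meta metadata (see [validate_metadata()]).
#' @param folds number of cross-validation folds (default 10).
#' @param seed fold-assignment seed.
#' @param nlambda,lambda.min.ratio lambda-grid shape.
#' @param adjust_covariates include unpenalized age/sex columns?
#' @return list with `coefficients` (features only, at the chosen lambda),
#'   `cv` (a `cv_penalized` record), and the underlying `cv.glmnet` fit.
#' @export
fit_lasso_cv <- function(m, meta, folds = 10, seed = 1L, nlambda = 100,
                         lambda.min.ratio = 1e-3, adjust_covariates = TRUE) {
  penalized_fit(m, meta, alpha_grid = 1, folds = folds, seed = seed,
                nlambda = nlambda, lambda.min.ratio = lambda.min.ratio,
                adjust_covariates = adjust_covariates)
}

#' Elastic-net logistic regression with cross-validated alpha and lambda
#'
#' Repeats the cross-validated fit over a grid of mixing parameters alpha
#' (default 0.1, 0.2, ..., 1.0), holding the fold assignment fixed across
#' alpha values so the cross-validation errors are comparable, and returns
#' the coefficients at the (alpha, lambda) pair with the smallest
#' cross-validated deviance (ties toward the sparser, larger alpha).
#'
#' @inheritParams fit_lasso_cv
#' @param alpha_grid mixing parameters in (0, 1\]; alpha = 1 is the LASSO.
#' @return as [fit_lasso_cv()].
#' @export
fit_elastic_net_cv <- function(m, meta, alpha_grid = seq(0.1, 1, by = 0.1),
                               folds = 10, seed = 1L, nlambda = 100,
                               lambda.min.ratio = 1e-3,
                               adjust_covariates = TRUE) {
  if (any(alpha_grid <= 0 | alpha_grid > 1))
    stop("`alpha_grid` must lie in (0, 1]")
  penalized_fit(m, meta, alpha_grid = alpha_grid, folds = folds, seed = seed,
                nlambda = nlambda, lambda.min.ratio = lambda.min.ratio,
                adjust_covariates = adjust_covariates)
}

#' Rank features by absolute coefficient magnitude
#'
#' Descending |coefficient|; exact zeros are unselected and imputed at rank
#' `n_total`; ties among nonzero coefficients break by feature id.
#'
#' @param coefficients named per-feature coefficient vector.
#' @param method ranking label (`"lasso"` or `"elastic_net"`).
#' @param n_total total feature count used as the imputed rank.
#' @return a [method_ranking()]; `score` is |coefficient|.
#' @export
rank_by_abs_coefficients <- function(coefficients, method = "lasso",
                                     n_total = length(coefficients)) {
  ids <- names(coefficients)
  if (is.null(ids)) stop("coefficients must be named by feature id")
  a <- abs(coefficients)
  rank_from_keys(method, ids, a, keys = list(-a, ids), selected = a > 0,
                 n_total = n_total)
}
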