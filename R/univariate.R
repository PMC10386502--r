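#' Covariate-adjusted univariate logistic regression for one feature
#'
#' Fits `outcome ~ feature + age + sex` by maximum likelihood and returns
#' the feature's Wald statistics. Quasi-complete separation is reported via
#' a flag (the Wald p-value is still returned); a non-converged or rank-
#' deficient fit (e.g. a constant feature) yields `NA` statistics and is
#' later rank-imputed.
#'
#' @param y binary outcome vector (0/1) with both classes present.
#' @param x numeric feature vector.
#' @param covariates numeric matrix of adjustment columns (age and a sex
#'   indicator); may be `NULL` for an unadjusted fit.
#' @return list with `beta`, `se`, `raw_p`, `converged`, `separation`.
#' @export
fit_univariate_logistic <- function(y, x, covariates = NULL) {
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  if (!all(is.finite(x))) stop("feature values must be finite")
  X <- cbind(`(Intercept)` = 1, x = x, covariates)
  if (nrow(X) <= ncol(X) + 1) stop("too few samples for the model")
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  na <- list(beta = NA_real_, se = NA_real_, raw_p = NA_real_,
             converged = FALSE, separation = FALSE)
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X)) return(na)
  beta <- fit$coefficients[["x"]]
  # Wald covariance from the weighted QR of the final IRLS iteration
  q <- fit$qr
  cov <- tryCatch(chol2inv(q$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(cov)) return(na)
  se <- sqrt(cov[2, 2])
  if (!is.finite(beta) || !is.finite(se) || se == 0) return(na)
  mu <- fit$fitted.values
  separation <- min(mu) < 1e-8 || max(mu) > 1 - 1e-8
  list(beta = beta, se = se, raw_p = 2 * pnorm(-abs(beta / se)),
       converged = TRUE, separation = separation)
}

#' Univariate logistic screen over all features
#'
#' Applies [fit_univariate_logistic()] to each feature of a scaled
#' abundance matrix, adjusting for age and sex.
#'
#' @param m scaled-stage [abundance_matrix()].
#' @param meta metadata (see [validate_metadata()]); `sex` may be a
#'   character/factor, encoded as a single female indicator.
#' @return data.frame: feature_id, beta, se, raw_p, converged, separation.
#' @export
univariate_screen <- function(m, meta) {
  meta <- validate_metadata(meta, m)
  covs <- cbind(age = meta$age, female = as.numeric(meta$sex == "female"))
  res <- lapply(seq_len(ncol(m)), function(j) {
    if (degenerate_features(m)[j])
      return(list(beta = NA_real_, se = NA_real_, raw_p = NA_real_,
                  converged = FALSE, separation = FALSE))
    fit_univariate_logistic(meta$outcome, m[, j], covs)
  })
  data.frame(feature_id = colnames(m),
             beta = vapply(res, `[[`, 0, "beta"),
             se = vapply(res, `[[`, 0, "se"),
             raw_p = vapply(res, `[[`, 0, "raw_p"),
             converged = vapply(res, `[[`, TRUE, "converged"),
             separation = vapply(res, `[[`, TRUE, "separation"),
             stringsAsFactors = FALSE)
}

#' Bonferroni adjustment
#'
#' Family-wise error control: each p-value is multiplied by the number of
#' comparisons `m` and capped at 1.
#'
#' @param raw_p p-values in \[0, 1\] (`NA` allowed, passed through).
#' @param m number of comparisons; defaults to the number of non-missing
#'   p-values and must be at least that.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(raw_p, m = sum(!is.na(raw_p))) {
  ok <- !is.na(raw_p)
  if (any(raw_p[ok] < 0 | raw_p[ok] > 1)) stop("p-values must lie in [0, 1]")
  if (m < sum(ok)) stop("`m` must be at least the number of p-values tested")
  out <- raw_p
  out[ok] <- pmin(1, m * raw_p[ok])
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the expected proportion of false
#' positives among discoveries: sort ascending, multiply the i-th order
#' statistic by m/i, enforce monotonicity from the largest down, cap at 1,
#' and return in the original order. Agrees with
#' `stats::p.adjust(method = "BH")` to floating-point rounding; the direct
#' form is kept so the adjusted values match the canonical step-up formula
#' bit for bit.
#'
#' @param raw_p p-values in \[0, 1\] (`NA` allowed, passed through).
#' @return BH-adjusted p-values.
#' @export
bh_fdr_adjust <- function(raw_p) {
  ok <- !is.na(raw_p)
  if (any(raw_p[ok] < 0 | raw_p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p <- raw_p[ok]
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(q))))
  out <- raw_p
  out[ok][o] <- adj
  out
}

#' Rank features by adjusted p-values
#'
#' Ascending order of adjusted p-value; ties are broken by the raw p-value,
#' then by feature id so reruns are bit-identical. Features without a
#' p-value (failed fits) are imputed at rank `n_total`.
#'
#' @param method ranking label (`"bonferroni"` or `"fdr"`).
#' @param feature_ids feature identifiers.
#' @param adjusted_p,raw_p aligned p-value vectors.
#' @param n_total total feature count used as the imputed rank.
#' @return a [method_ranking()]; `score` is the adjusted p-value.
#' @export
rank_by_pvalues <- function(method, feature_ids, adjusted_p, raw_p,
                            n_total = length(feature_ids)) {
  if (length(adjusted_p) != length(feature_ids) ||
      length(raw_p) != length(feature_ids))
    stop("p-value vectors must align with feature ids")
  ok <- !is.na(adjusted_p) & !is.na(raw_p)
  rank_from_keys(method, feature_ids, adjusted_p,
                 keys = list(adjusted_p, raw_p, feature_ids),
                 selected = ok, n_total = n_total)
}

#' Univariate rankings with Bonferroni and BH-FDR correction
#'
#' Runs the screen once and returns both multiple-testing rankings, which
#' the aggregation stage treats as two separate methods.
#'
#' @inheritParams univariate_screen
#' @param n_total total feature count used as the imputed rank.
#' @return list with elements `bonferroni` and `fdr` (each a
#'   [method_ranking()]) and `screen` (the per-feature fit table).
#' @export
rank_univariate <- function(m, meta, n_total = ncol(m)) {
  screen <- univariate_screen(m, meta)
  m_tests <- sum(!is.na(screen$raw_p))
  bon <- bonferroni_adjust(screen$raw_p, m = m_tests)
  fdr <- bh_fdr_adjust(screen$raw_p)
  list(bonferroni = rank_by_pvalues("bonferroni", screen$feature_id, bon,
                                    screen$raw_p, n_total),
       fdr = rank_by_pvalues("fdr", screen$feature_id, fdr, screen$raw_p,
                             n_total),
       screen = screen)
}
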