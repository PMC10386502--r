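# Convergence/divergence diagnostics: how intercorrelated are the features
# a method puts in its top k? Methods blind to feature correlation tend to
# fill their top list with members of the same correlated block
# (convergent); decorrelating or sparsity-inducing methods spread their
# picks across blocks (divergent).

#' Top-k features of a ranking
#'
#' The k best-ranked non-imputed features. If fewer than k features were
#' scored, all of them are returned with a warning.
#'
#' @param ranking a [method_ranking()].
#' @param k number of features (default 50).
#' @return character vector of feature ids in rank order.
#' @export
top_k <- function(ranking, k = 50) {
  if (k <= 0) stop("`k` must be positive")
  sel <- ranking[!ranking$imputed, , drop = FALSE]
  sel <- sel[order(sel$rank), , drop = FALSE]
  if (nrow(sel) < k) {
    warning(sprintf("only %d features scored by '%s'; returning all of them",
                    nrow(sel), attr(ranking, "method")))
    k <- nrow(sel)
  }
  sel$feature_id[seq_len(k)]
}

#' Pearson correlation matrix of selected features
#'
#' Pairwise Pearson correlations of the given feature columns. Degenerate
#' (zero-variance) columns get correlation 0 with everything (diagonal 1)
#' and are recorded in the `degenerate` attribute.
#'
#' @param m an [abundance_matrix()] (typically preprocessed).
#' @param ids feature ids to correlate.
#' @return k x k correlation matrix.
#' @export
correlation_matrix <- function(m, ids) {
  if (nrow(m) < 3) stop("need at least 3 samples")
  miss <- setdiff(ids, colnames(m))
  if (length(miss))
    stop("features absent from matrix: ", paste(head(miss, 5), collapse = ", "))
  v <- unclass(m)[, ids, drop = FALSE]
  s <- apply(v, 2, sd)
  deg <- s == 0
  R <- suppressWarnings(cor(v))
  if (any(deg)) {
    R[deg, ] <- 0
    R[, deg] <- 0
  }
  diag(R) <- 1
  attr(R, "degenerate") <- deg
  R
}

#' Fraction of highly correlated pairs and features
#'
#' Two readings of "share of the top k that is highly correlated", emitted
#' side by side: `pair_fraction`, the share of unordered off-diagonal pairs
#' with |R| at or above the threshold; and `participation`, the share of
#' features involved in at least one such pair.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param high_threshold |R| threshold for "highly correlated"
#'   (default 0.4).
#' @return list: `pair_fraction`, `participation`, `r_range` (range of
#'   off-diagonal |R|), `high_threshold`.
#' @export
fraction_correlated <- function(corr, high_threshold = 0.4) {
  k <- nrow(corr)
  if (k < 2) stop("need at least 2 features")
  a <- abs(corr[upper.tri(corr)])
  high <- corr
  diag(high) <- 0
  involved <- rowSums(abs(high) >= high_threshold) > 0
  list(pair_fraction = mean(a >= high_threshold),
       participation = mean(involved),
       r_range = range(a),
       high_threshold = high_threshold)
}

#' Classify a method's top-k profile as convergent or divergent
#'
#' Operational rule: a method is called convergent when at least
#' `rule_threshold` of its top-k features participate in at least one
#' highly correlated pair (boundary inclusive), divergent otherwise.
#'
#' @param participation feature-participation fraction from
#'   [fraction_correlated()].
#' @param rule_threshold decision threshold (default 0.5).
#' @return `"convergent"` or `"divergent"`.
#' @export
classify_method <- function(participation, rule_threshold = 0.5) {
  if (participation >= rule_threshold) "convergent" else "divergent"
}

#' Convergence summary for one method
#'
#' Bundles the top-k selection, its correlation matrix, both
#' highly-correlated fractions and the convergent/divergent label.
#'
#' @param ranking a [method_ranking()].
#' @param m preprocessed [abundance_matrix()] the correlations are
#'   measured on.
#' @param k top-list size (default 50).
#' @param high_threshold |R| threshold for "highly correlated".
#' @param rule_threshold participation threshold for the convergent label.
#' @return list of class `convergence_summary`: `method`, `top_k_ids`,
#'   `corr`, `pair_fraction`, `participation`, `r_range`, `high_threshold`,
#'   `rule_threshold`, `label`.
#' @export
convergence_summary <- function(ranking, m, k = 50, high_threshold = 0.4,
                                rule_threshold = 0.5) {
  ids <- top_k(ranking, k)
  R <- correlation_matrix(m, ids)
  fr <- fraction_correlated(R, high_threshold)
  structure(list(method = attr(ranking, "method"), top_k_ids = ids,
                 corr = R, pair_fraction = fr$pair_fraction,
                 participation = fr$participation, r_range = fr$r_range,
                 high_threshold = high_threshold,
                 rule_threshold = rule_threshold,
                 label = classify_method(fr$participation, rule_threshold)),
            class = "convergence_summary")
}

#' @export
print.convergence_summary <- function(x, ...) {
  cat(sprintf(
    "convergence_summary [%s]: top %d, %.0f%% of pairs and %.0f%% of features |R| >= %.2f -> %s\n",
    x$method, length(x$top_k_ids), 100 * x$pair_fraction,
    100 * x$participation, x$high_threshold, x$label))
  invisible(x)
}
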