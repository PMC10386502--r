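#' Construct a per-method feature ranking
#'
#' The common output contract of every ranking method: one row per feature
#' with the method-specific score, an integer rank (1 = most important), and
#' an imputation flag. Features a method does not score or select (a zero
#' LASSO coefficient, a feature unused by any boosted tree, a failed
#' univariate fit) all receive the same imputed rank `n_total`, the total
#' feature count, so that rankings from sparse and dense methods live on a
#' common scale during aggregation.
#'
#' @param method method label, one of `"bonferroni"`, `"fdr"`, `"lasso"`,
#'   `"elastic_net"`, `"random_forest"`, `"sda"`, `"xgboost"`.
#' @param feature_ids character vector of feature identifiers.
#' @param score numeric per-feature score (semantics depend on the method);
#'   may be `NA` for imputed features.
#' @param rank integer per-feature rank.
#' @param imputed logical per-feature imputation flag.
#' @param n_total total feature count used as the imputed rank.
#' @return data.frame of class `method_ranking` with attributes `method` and
#'   `n_total`.
#' @export
method_ranking <- function(method, feature_ids, score, rank, imputed,
                           n_total = length(feature_ids)) {
  methods <- c("bonferroni", "fdr", "lasso", "elastic_net", "random_forest",
               "sda", "xgboost")
  if (!method %in% methods)
    stop("unknown method label '", method, "'")
  n <- length(feature_ids)
  stopifnot(length(score) == n, length(rank) == n, length(imputed) == n)
  if (any(!imputed & !is.finite(score)))
    stop("non-imputed features must have finite scores")
  r <- sort(rank[!imputed])
  if (length(r) && !identical(as.integer(r), seq_along(r)))
    stop("non-imputed ranks must be exactly 1..s")
  if (any(imputed & rank != n_total))
    stop("imputed features must carry rank n_total = ", n_total)
  structure(data.frame(feature_id = as.character(feature_ids), score = score,
                       rank = as.integer(rank), imputed = imputed,
                       stringsAsFactors = FALSE),
            method = method, n_total = n_total,
            class = c("method_ranking", "data.frame"))
}

#' @export
print.method_ranking <- function(x, ...) {
  cat(sprintf("method_ranking [%s]: %d features, %d scored, %d imputed\n",
              attr(x, "method"), nrow(x), sum(!x$imputed), sum(x$imputed)))
  print(utils::head(as.data.frame(x)[order(x$rank), ], 5))
  invisible(x)
}

# internal: build a method_ranking from a descending-score criterion.
# `keys` is a list of vectors passed to order() (first = primary); only
# features with selected = TRUE receive ranks 1..s, the rest are imputed.
rank_from_keys <- function(method, feature_ids, score, keys, selected,
                           n_total = length(feature_ids)) {
  n <- length(feature_ids)
  rank <- rep.int(n_total, n)
  if (any(selected)) {
    ord <- do.call(order, lapply(keys, function(k) k[selected]))
    rank[which(selected)[ord]] <- seq_len(sum(selected))
  }
  method_ranking(method, feature_ids, score, rank, !selected, n_total)
}

#' Write a ranking to TSV
#' @param ranking a [method_ranking()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ranking_tsv <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
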