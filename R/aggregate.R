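# Cross-method rank aggregation: a fully populated feature x method rank
# matrix (unscored features imputed at the total feature count), summarized
# by the integrated (sum), difference (max - min) and variance ranks.

#' Assemble the imputed rank matrix
#'
#' Binds the per-method rank columns over a common feature universe.
#' Features a method did not score carry that method's imputed rank, which
#' the [method_ranking()] contract fixes at `n_total`, the total feature
#' count; the matrix is therefore fully populated.
#'
#' @param rankings named list of [method_ranking()] objects over the same
#'   feature universe (names default to each ranking's method label).
#' @param n_total total feature count; every ranking's imputed rank must
#'   equal it.
#' @return integer matrix, features x methods, rownames = feature ids.
#' @export
impute_missing_ranks <- function(rankings, n_total) {
  if (!length(rankings)) stop("need at least one ranking")
  if (is.null(names(rankings)))
    names(rankings) <- vapply(rankings, attr, "", "method")
  ids <- rankings[[1]]$feature_id
  cols <- lapply(rankings, function(r) {
    if (!identical(sort(r$feature_id), sort(ids)))
      stop("rankings cover different feature universes")
    if (max(r$rank) > n_total)
      stop("observed rank exceeds n_total")
    r$rank[match(ids, r$feature_id)]
  })
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  m
}

#' Integrated rank: per-feature sum of method ranks
#' @param rank_matrix imputed rank matrix from [impute_missing_ranks()].
#' @return named numeric vector; smaller = more consistently prioritized.
#' @export
integrated_rank <- function(rank_matrix) rowSums(rank_matrix)

#' Difference rank: per-feature range of method ranks
#' @inheritParams integrated_rank
#' @return named numeric vector (max - min); larger = more disagreement.
#' @export
difference_rank <- function(rank_matrix) {
  apply(rank_matrix, 1, max) - apply(rank_matrix, 1, min)
}

#' Variance rank: per-feature sample variance of method ranks
#' @inheritParams integrated_rank
#' @return named numeric vector (n-1 denominator).
#' @export
variance_rank <- function(rank_matrix) {
  if (ncol(rank_matrix) < 2) stop("variance rank needs at least 2 methods")
  mu <- rowMeans(rank_matrix)
  rowSums((rank_matrix - mu)^2) / (ncol(rank_matrix) - 1)
}

#' Aggregate per-method rankings into cross-method statistics
#'
#' Builds the imputed rank matrix and attaches the integrated, difference
#' and variance ranks per feature.
#'
#' @inheritParams impute_missing_ranks
#' @return data.frame of class `aggregate_ranking`: `feature_id`, one rank
#'   column per method, `integrated`, `difference`, `variance`; attribute
#'   `n_total`.
#' @export
aggregate_ranks <- function(rankings, n_total) {
  m <- impute_missing_ranks(rankings, n_total)
  out <- data.frame(feature_id = rownames(m), m,
                    integrated = integrated_rank(m),
                    difference = difference_rank(m),
                    variance = variance_rank(m),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  structure(out, n_total = n_total,
            methods = colnames(m),
            class = c("aggregate_ranking", "data.frame"))
}

#' Restrict an aggregate ranking to the best-integrated features
#'
#' Keeps the `n` features with the smallest integrated rank (ties at the
#' boundary broken by feature id), the window on which the difference and
#' variance ranks are typically reported.
#'
#' @param aggregate an [aggregate_ranks()] result.
#' @param n number of features to keep (default 500).
#' @return the restricted `aggregate_ranking`, ordered by integrated rank.
#' @export
focus_top <- function(aggregate, n = 500) {
  if (n < 1 || n > nrow(aggregate)) stop("`n` must lie in [1, feature count]")
  ord <- order(aggregate$integrated, aggregate$feature_id)
  out <- aggregate[ord[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_total = attr(aggregate, "n_total"),
            methods = attr(aggregate, "methods"),
            class = c("aggregate_ranking", "data.frame"))
}
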