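# Random-forest ranking: OOB-tuned forest, OOB permutation importance as
# the primary score, average minimal depth as tie-break and optional
# selection gate. The forest itself is fit with the randomForest package;
# minimal depth is computed here by walking each tree.

#' Tune and fit a classification random forest
#'
#' Grid-searches `mtry` (features tried per split) and `nodesize` (minimal
#' terminal-node size) by out-of-bag misclassification, then refits the
#' winning pair on all data with permutation importance enabled. Ties in
#' OOB error break toward the smaller `mtry`, then the larger `nodesize`
#' (the more regularized model). All randomness is governed by `seed`, so
#' identical calls produce identical forests.
#'
#' @param m scaled-stage [abundance_matrix()] (any numeric matrix works).
#' @param y binary outcome vector (0/1).
#' @param mtry_grid candidate `mtry` values; default `sqrt(p)`, `p/10`,
#'   `p/3` (deduplicated, floored at 1).
#' @param nodesize_grid candidate terminal-node sizes (default 5, 15, 50).
#' @param n_trees trees per forest (default 500).
#' @param seed RNG seed for bagging and permutation importance.
#' @return list of class `forest_model`: the `randomForest` fit, chosen
#'   `mtry`/`nodesize`, `oob_error`, `n_trees`, `seed`, and the tuning
#'   trace.
#' @export
tune_and_fit_forest <- function(m, y, mtry_grid = NULL,
                                nodesize_grid = c(5, 15, 50),
                                n_trees = 500, seed = 1L) {
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  if (n_trees < 50) stop("`n_trees` must be >= 50")
  p <- ncol(m)
  if (is.null(mtry_grid))
    mtry_grid <- unique(pmax(1L, floor(c(sqrt(p), p / 10, p / 3))))
  if (!length(mtry_grid) || !length(nodesize_grid)) stop("empty tuning grid")
  yf <- factor(y, levels = c(0, 1))
  X <- unclass(m)
  grid <- expand.grid(mtry = sort(mtry_grid), nodesize = nodesize_grid)
  grid$oob <- NA_real_
  for (i in seq_len(nrow(grid))) {
    set.seed(seed)
    rf <- randomForest::randomForest(X, yf, ntree = n_trees,
                                     mtry = grid$mtry[i],
                                     nodesize = grid$nodesize[i])
    grid$oob[i] <- rf$err.rate[n_trees, "OOB"]
  }
  cand <- grid[grid$oob == min(grid$oob), , drop = FALSE]
  cand <- cand[order(cand$mtry, -cand$nodesize), , drop = FALSE]
  best <- cand[1, ]
  set.seed(seed)
  rf <- randomForest::randomForest(X, yf, ntree = n_trees, mtry = best$mtry,
                                   nodesize = best$nodesize,
                                   importance = TRUE)
  structure(list(rf = rf, mtry = best$mtry, nodesize = best$nodesize,
                 n_trees = n_trees, oob_error = rf$err.rate[n_trees, "OOB"],
                 seed = seed, tuning = grid,
                 feature_ids = colnames(m)),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees, mtry = %d, nodesize = %d, OOB error = %.3f\n",
              x$n_trees, x$mtry, x$nodesize, x$oob_error))
  invisible(x)
}

# internal: minimal depth of each feature in one parsed tree.
# `tree` is a matrix in randomForest::getTree() layout: columns
# "left daughter", "right daughter", "split var", "status"; daughters
# always have larger row indices than their parent, so a single forward
# pass assigns depths. Returns list(min_depth = named by feature index for
# features that split somewhere, max_depth = deepest node depth).
tree_min_depth <- function(tree, n_features) {
  nn <- nrow(tree)
  depth <- rep.int(NA_real_, nn)
  depth[1] <- 0
  for (i in seq_len(nn)) {
    ld <- tree[i, "left daughter"]; rd <- tree[i, "right daughter"]
    if (ld > 0) depth[ld] <- depth[i] + 1
    if (rd > 0) depth[rd] <- depth[i] + 1
  }
  split_rows <- which(tree[, "split var"] > 0)
  md <- rep.int(Inf, n_features)
  for (i in split_rows) {
    v <- tree[i, "split var"]
    if (depth[i] < md[v]) md[v] <- depth[i]
  }
  list(min_depth = md, max_depth = max(depth, na.rm = TRUE))
}

# internal: forest-average minimal depth over a list of parsed trees;
# features absent from a tree contribute that tree's (max depth + 1).
min_depth_trees <- function(trees, n_features) {
  acc <- numeric(n_features)
  for (tr in trees) {
    d <- tree_min_depth(tr, n_features)
    md <- d$min_depth
    md[!is.finite(md)] <- d$max_depth + 1
    acc <- acc + md
  }
  acc / length(trees)
}

#' Average minimal depth of each feature in a forest
#'
#' Per tree, a feature's minimal depth is the depth of the shallowest node
#' splitting on it (root = 0); a feature absent from a tree is penalized
#' with that tree's maximum depth + 1. The returned value averages over
#' trees; smaller means more important.
#'
#' @param model a `forest_model` from [tune_and_fit_forest()].
#' @return named numeric vector of average minimal depths.
#' @export
minimal_depth <- function(model) {
  if (!inherits(model, "forest_model")) stop("need a forest_model")
  ntree <- model$rf$ntree
  if (ntree < 1) stop("empty forest")
  p <- length(model$feature_ids)
  trees <- lapply(seq_len(ntree), function(k)
    randomForest::getTree(model$rf, k, labelVar = FALSE))
  setNames(min_depth_trees(trees, p), model$feature_ids)
}

#' Out-of-bag permutation importance
#'
#' The increase in out-of-bag misclassification when a feature's
#' out-of-bag values are permuted, averaged over trees (the accuracy-based
#' importance computed during the forest fit, unscaled). Deterministic for
#' a fixed fitting seed.
#'
#' @param model a `forest_model` from [tune_and_fit_forest()].
#' @return named numeric vector of importances.
#' @export
forest_importance <- function(model) {
  if (!inherits(model, "forest_model")) stop("need a forest_model")
  imp <- randomForest::importance(model$rf, type = 1, scale = FALSE)[, 1]
  setNames(as.numeric(imp), model$feature_ids)
}

#' Rank features by forest importance and minimal depth
#'
#' Primary order is descending permutation importance; average minimal
#' depth (ascending) breaks ties, then feature id. With `selection = "on"`
#' features whose average minimal depth exceeds the forest-average depth
#' threshold are treated as unselected and imputed at rank `n_total`;
#' `ranking = "depth"` switches the primary order to ascending minimal
#' depth.
#'
#' @param minimal_depths named vector from [minimal_depth()].
#' @param importances named vector from [forest_importance()].
#' @param selection `"off"` (default: every feature ranked) or `"on"`.
#' @param ranking `"importance"` (default) or `"depth"`.
#' @param n_total total feature count used as the imputed rank.
#' @return a [method_ranking()] with method `"random_forest"`.
#' @export
rank_forest <- function(minimal_depths, importances,
                        selection = c("off", "on"),
                        ranking = c("importance", "depth"),
                        n_total = length(importances)) {
  selection <- match.arg(selection)
  ranking <- match.arg(ranking)
  ids <- names(importances)
  if (is.null(ids) || !identical(ids, names(minimal_depths)))
    stop("importances and minimal_depths must be named and aligned")
  sel <- if (selection == "on") minimal_depths <= mean(minimal_depths)
         else rep(TRUE, length(ids))
  keys <- if (ranking == "importance")
    list(-importances, minimal_depths, ids)
  else
    list(minimal_depths, -importances, ids)
  score <- if (ranking == "importance") importances else -minimal_depths
  rank_from_keys("random_forest", ids, score, keys = keys, selected = sel,
                 n_total = n_total)
}
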