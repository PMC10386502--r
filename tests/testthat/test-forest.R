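# hand-built trees in randomForest::getTree layout for the minimal-depth
# oracle: columns "left daughter", "right daughter", "split var", "status"
toy_tree <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- c("left daughter", "right daughter", "split var", "status")
  m
}

test_that("minimal depth matches a hand-walk of toy trees", {
  # tree 1: root splits on feature 1, both children terminal (max depth 1)
  t1 <- toy_tree(list(c(2, 3, 1, 1), c(0, 0, 0, -1), c(0, 0, 0, -1)))
  # tree 2: chain of splits on features 2,3,2 reaching depth 3
  t2 <- toy_tree(list(c(2, 3, 2, 1), c(4, 5, 3, 1), c(0, 0, 0, -1),
                      c(6, 7, 2, 1), c(0, 0, 0, -1), c(0, 0, 0, -1),
                      c(0, 0, 0, -1)))
  md <- metarank:::min_depth_trees(list(t1, t2), 3)
  # feature 1: depth 0 in tree 1, absent in tree 2 (max depth 3) -> (0+4)/2
  expect_equal(md[1], 2)
  # feature 2: absent in tree 1 (max depth 1 -> 2), depth 0 in tree 2
  expect_equal(md[2], 1)
  # feature 3: absent in tree 1 -> 2, depth 1 in tree 2
  expect_equal(md[3], 1.5)
})

test_that("root-splitting and absent features hit the depth conventions", {
  t1 <- toy_tree(list(c(2, 3, 1, 1), c(0, 0, 0, -1), c(0, 0, 0, -1)))
  md <- metarank:::min_depth_trees(list(t1, t1), 2)
  expect_equal(md[1], 0)       # splits every root
  expect_equal(md[2], 2)       # absent from every tree of depth 1 -> 1 + 1
})

test_that("forest tuning tracks the OOB error and is deterministic", {
  sim <- small_sim(seed = 71, n = 300, n_blocks = 4, block_size = 5,
                   n_signal_blocks = 2, beta_signal = 2)
  pre <- preprocess_abundance(sim$abundance, sim$metadata)
  fm1 <- tune_and_fit_forest(pre, sim$metadata$outcome, mtry_grid = c(2, 4),
                             nodesize_grid = c(5, 15), n_trees = 100, seed = 5)
  fm2 <- tune_and_fit_forest(pre, sim$metadata$outcome, mtry_grid = c(2, 4),
                             nodesize_grid = c(5, 15), n_trees = 100, seed = 5)
  expect_equal(fm1$tuning, fm2$tuning)
  expect_identical(forest_importance(fm1), forest_importance(fm2))
  expect_identical(minimal_depth(fm1), minimal_depth(fm2))
  expect_equal(fm1$oob_error, fm2$oob_error)
  best <- fm1$tuning[which.min(fm1$tuning$oob), ]
  expect_equal(fm1$mtry, best$mtry)
})

test_that("pure-noise forests sit at the majority-class error", {
  set.seed(72)
  n <- 300
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("S%05d", 1:n), sprintf("M%06d", 1:20)))
  y <- rbinom(n, 1, 0.4)
  fm <- tune_and_fit_forest(abundance_matrix(X, stage = "scaled"), y,
                            mtry_grid = 4, nodesize_grid = 5, n_trees = 200,
                            seed = 7)
  expect_lt(abs(fm$oob_error - min(mean(y), 1 - mean(y))), 0.05)
  # and every noise importance is near zero
  imp <- forest_importance(fm)
  expect_lt(max(abs(imp)), 0.02)
})

test_that("a dominant feature drives the OOB error toward zero", {
  set.seed(73)
  n <- 1000
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("S%05d", 1:n), sprintf("M%06d", 1:10)))
  y <- as.integer(X[, 1] + rnorm(n, sd = 0.1) > 0)
  fm <- tune_and_fit_forest(abundance_matrix(X, stage = "scaled"), y,
                            mtry_grid = 3, nodesize_grid = 5, n_trees = 100,
                            seed = 9)
  expect_lt(fm$oob_error, 0.1)
  expect_equal(names(which.max(forest_importance(fm))), "M000001")
  expect_equal(names(which.min(minimal_depth(fm))), "M000001")
})

test_that("the planted causal feature wins the importance ranking", {
  wins <- vapply(1:100, function(i) {
    set.seed(900 + i)
    n <- 300
    X <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(sprintf("S%05d", 1:n), sprintf("M%06d", 1:20)))
    y <- rbinom(n, 1, plogis(2.5 * X[, 1]))
    fm <- tune_and_fit_forest(abundance_matrix(X, stage = "scaled"), y,
                              mtry_grid = 4, nodesize_grid = 5,
                              n_trees = 100, seed = i)
    imp <- forest_importance(fm)
    imp[1] > 0 && which.max(imp) == 1
  }, TRUE)
  expect_gte(sum(wins), 90)
})

test_that("forest ranking uses importance, then depth, then the gate", {
  imp <- setNames(c(0.2, 0, 0.1), c("A", "B", "C"))
  dep <- setNames(c(1, 3, 2), c("A", "B", "C"))
  r <- rank_forest(dep, imp)
  expect_equal(r$rank, c(1L, 3L, 2L))

  tied <- setNames(c(0.1, 0.1), c("A", "B"))
  deps <- setNames(c(1.0, 0.5), c("A", "B"))
  r2 <- rank_forest(deps, tied)
  expect_equal(r2$rank, c(2L, 1L))  # deeper feature ranked lower

  r3 <- rank_forest(dep, imp, selection = "on", n_total = 100)
  expect_true(r3$imputed[r3$feature_id == "B"])   # depth 3 > mean depth 2
  expect_equal(r3$rank[r3$feature_id == "B"], 100L)
})

test_that("boosting tuning is seeded-deterministic and null-calibrated", {
  set.seed(74)
  n <- 300
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("S%05d", 1:n), sprintf("M%06d", 1:20)))
  y <- rbinom(n, 1, 0.4)
  m <- abundance_matrix(X, stage = "scaled")
  grid <- data.frame(max_depth = c(2, 3), eta = 0.1)
  b1 <- tune_and_fit_xgb(m, y, param_grid = grid, seed = 3, nrounds_max = 60)
  b2 <- tune_and_fit_xgb(m, y, param_grid = grid, seed = 3, nrounds_max = 60)
  expect_equal(b1$tuning, b2$tuning)
  expect_identical(rank_xgb_gain(b1)$score, rank_xgb_gain(b2)$score)
  expect_lt(abs(b1$cv_error - min(mean(y), 1 - mean(y))), 0.05)
})

test_that("a strong single signal concentrates the gain", {
  wins <- vapply(1:100, function(i) {
    set.seed(1100 + i)
    n <- 300
    X <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(sprintf("S%05d", 1:n), sprintf("M%06d", 1:20)))
    y <- rbinom(n, 1, plogis(3 * X[, 1]))
    bm <- tune_and_fit_xgb(abundance_matrix(X, stage = "scaled"), y,
                           param_grid = data.frame(max_depth = 2, eta = 0.3),
                           seed = i, nrounds_max = 40, early_stopping = 10)
    r <- rank_xgb_gain(bm)
    r$score[r$feature_id == "M000001"] > 0.5
  }, TRUE)
  expect_gte(sum(wins), 90)
})

test_that("gain ranking normalizes, imputes unused features, breaks ties by id", {
  r <- rank_xgb_gain(setNames(c(30, 70), c("A", "B")))
  expect_equal(r$score, c(0.3, 0.7))
  expect_equal(r$rank, c(2L, 1L))

  r1 <- rank_xgb_gain(setNames(c(0, 12, 0), c("A", "B", "C")), n_total = 500)
  expect_equal(r1$score[2], 1)
  expect_equal(r1$rank, c(500L, 1L, 500L))
  expect_equal(r1$imputed, c(TRUE, FALSE, TRUE))

  r3 <- rank_xgb_gain(setNames(c(5, 5, 5), c("B", "C", "A")))
  expect_equal(r3$score, rep(1 / 3, 3))
  expect_equal(r3$rank[match(c("A", "B", "C"), r3$feature_id)], 1:3)

  # gain fractions from a fitted model sum to 1 over used features
  sim <- small_sim(seed = 75, n = 150, n_blocks = 3, block_size = 5)
  pre <- preprocess_abundance(sim$abundance, sim$metadata)
  bm <- tune_and_fit_xgb(pre, sim$metadata$outcome,
                         param_grid = data.frame(max_depth = 2, eta = 0.3),
                         seed = 1, nrounds_max = 30, early_stopping = 10)
  rr <- rank_xgb_gain(bm)
  expect_equal(sum(rr$score[!rr$imputed]), 1, tolerance = 1e-9)
})
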