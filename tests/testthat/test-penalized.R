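# shared small cohort for the structural checks
pen_sim <- small_sim(seed = 51, n = 200, n_blocks = 6, block_size = 10,
                     n_signal_blocks = 2, beta_signal = 1.5)
pen_pre <- preprocess_abundance(pen_sim$abundance, pen_sim$metadata)

test_that("above the analytic lambda-max all feature coefficients vanish", {
  meta <- pen_sim$metadata
  fit <- fit_lasso_cv(pen_pre, meta, seed = 1, adjust_covariates = FALSE)
  y <- meta$outcome
  lambda_max <- max(abs(crossprod(unclass(pen_pre), y - mean(y)))) / length(y)
  co <- coef(fit$fit, s = lambda_max * 1.05)
  expect_true(all(as.numeric(co)[-1] == 0))
  expect_equal(fit$cv$lambda_grid[1], lambda_max, tolerance = 1e-6)
})

test_that("a strongly planted feature tops the LASSO ranking", {
  hits <- 0
  for (i in 1:100) {
    set.seed(400 + i)
    n <- 1000
    X <- matrix(rnorm(n * 201), n, 201,
                dimnames = list(sprintf("S%05d", 1:n), sprintf("M%06d", 1:201)))
    y <- rbinom(n, 1, plogis(2 * X[, 1]))
    meta <- manual_meta(n, outcome = y)
    m <- abundance_matrix(X, stage = "scaled")
    fit <- fit_lasso_cv(m, meta, folds = 5, seed = i, nlambda = 40,
                        lambda.min.ratio = 0.02, adjust_covariates = FALSE)
    if (which.max(abs(fit$coefficients)) == 1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("duplicating the signal feature roughly preserves total weight", {
  set.seed(52)
  n <- 600
  x <- rnorm(n)
  noise <- matrix(rnorm(n * 30), n, 30)
  y <- rbinom(n, 1, plogis(1.5 * x))
  meta <- manual_meta(n, outcome = y)
  X2 <- cbind(x, x, noise)
  colnames(X2) <- sprintf("M%06d", 1:32)
  rownames(X2) <- meta$sample_id
  X1 <- X2[, -2]
  f2 <- fit_lasso_cv(abundance_matrix(X2, stage = "scaled"), meta, seed = 3,
                     adjust_covariates = FALSE)
  f1 <- fit_lasso_cv(abundance_matrix(X1, stage = "scaled"), meta, seed = 3,
                     adjust_covariates = FALSE)
  pair <- sum(abs(f2$coefficients[1:2]))
  single <- abs(f1$coefficients[1])
  expect_lt(abs(pair - single) / single, 0.2)
})

test_that("elastic net with alpha grid {1} reproduces the LASSO fit", {
  las <- fit_lasso_cv(pen_pre, pen_sim$metadata, seed = 5)
  ene <- fit_elastic_net_cv(pen_pre, pen_sim$metadata, alpha_grid = 1, seed = 5)
  expect_identical(las$coefficients, ene$coefficients)
  expect_equal(las$cv$chosen_lambda, ene$cv$chosen_lambda)
})

test_that("small alpha shows the grouping effect on duplicated features", {
  set.seed(53)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x))
  X <- cbind(x, x + rnorm(n, sd = 1e-6), matrix(rnorm(n * 20), n, 20))
  colnames(X) <- sprintf("M%06d", 1:22)
  rownames(X) <- sprintf("S%05d", 1:n)
  X <- scale(X)
  meta <- manual_meta(n, outcome = y)
  fit <- fit_elastic_net_cv(abundance_matrix(X, stage = "scaled"), meta,
                            alpha_grid = 0.1, seed = 7,
                            adjust_covariates = FALSE)
  co <- fit$coefficients[1:2]
  expect_true(all(co != 0))
  expect_identical(unname(sign(co[1])), unname(sign(co[2])))
})

test_that("under the null the chosen model is sparse", {
  zeros <- vapply(1:20, function(i) {
    sim <- small_sim(seed = 600 + i, n = 150, n_blocks = 10, block_size = 10,
                     n_signal_blocks = 0, beta_signal = 0)
    pre <- preprocess_abundance(sim$abundance, sim$metadata)
    fit <- fit_lasso_cv(pre, sim$metadata, folds = 5, seed = i, nlambda = 40,
                        lambda.min.ratio = 0.05)
    mean(fit$coefficients == 0)
  }, 0)
  expect_gte(mean(zeros >= 0.9), 0.9)
})

test_that("coefficient ranking imputes zeros and breaks ties by id", {
  co <- setNames(c(0.5, -2, 0), c("A", "B", "C"))
  r <- rank_by_abs_coefficients(co, "lasso", n_total = 3)
  expect_equal(r$rank, c(2L, 1L, 3L))
  expect_equal(r$imputed, c(FALSE, FALSE, TRUE))

  r0 <- rank_by_abs_coefficients(setNames(numeric(3), c("A", "B", "C")),
                                 "lasso", n_total = 500)
  expect_true(all(r0$imputed) && all(r0$rank == 500L))

  rt <- rank_by_abs_coefficients(setNames(c(-1, 1), c("B", "A")), "lasso")
  expect_equal(rt$rank[match(c("A", "B"), rt$feature_id)], 1:2)
})

test_that("the active set grows along the lambda path", {
  # L1 active sets are not strictly nested: a variable can leave the set as
  # a correlated partner enters, so occasional single-feature drops are
  # expected; the trend over the descending lambda grid must still be
  # strongly increasing.
  fit <- fit_lasso_cv(pen_pre, pen_sim$metadata, seed = 9)
  nz <- as.integer(fit$cv$nonzero_path)
  d <- diff(nz)
  expect_true(all(diff(fit$cv$lambda_grid) < 0))
  expect_true(all(d >= -2))
  expect_lt(sum(d < 0) / length(d), 0.1)
  expect_gt(nz[length(nz)], nz[1])
  expect_gt(cor(seq_along(nz), nz, method = "spearman"), 0.95)
})

test_that("seeded penalized fits are bit-identical and scale-invariant", {
  f1 <- fit_lasso_cv(pen_pre, pen_sim$metadata, seed = 11)
  f2 <- fit_lasso_cv(pen_pre, pen_sim$metadata, seed = 11)
  expect_identical(f1$coefficients, f2$coefficients)

  # multiplying a raw feature by 10 dissolves in log + batch normalization
  raw2 <- unclass(pen_sim$abundance)
  raw2[, 4] <- raw2[, 4] * 10
  pre2 <- preprocess_abundance(abundance_matrix(raw2, stage = "raw"),
                               pen_sim$metadata)
  f3 <- fit_lasso_cv(pre2, pen_sim$metadata, seed = 11)
  r1 <- rank_by_abs_coefficients(f1$coefficients, "lasso")
  r3 <- rank_by_abs_coefficients(f3$coefficients, "lasso")
  expect_identical(r1$rank, r3$rank)
})
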