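test_that("t-scores reduce to the textbook statistic without shrinkage", {
  # group means 1 and 0, pooled SD 1, n = 2 per group
  d <- 1 / sqrt(2)
  m <- manual_abundance(matrix(c(1 + d, 1 - d, d, -d), 4, 1),
                        stage = "scaled")
  t <- t_scores(m, c(1, 1, 0, 0), lambda_var = 0)
  expect_equal(as.numeric(t), 1)
})

test_that("full variance shrinkage collapses every SD to the median", {
  sim <- small_sim(seed = 61, n = 60)
  pre <- preprocess_abundance(sim$abundance, sim$metadata)
  t1 <- t_scores(pre, sim$metadata$outcome, lambda_var = 1)
  s <- attr(t1, "s")
  expect_true(all(abs(s - s[1]) < 1e-12))
})

test_that("permuted labels keep max |t| below the Bonferroni bound", {
  set.seed(62)
  n <- 500; p <- 50
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%05d", 1:n), sprintf("M%06d", 1:p)))
  m <- abundance_matrix(X, stage = "scaled")
  bound <- qnorm(1 - 0.05 / (2 * p))
  inside <- vapply(1:100, function(i) {
    y <- sample(rep(0:1, n / 2))
    max(abs(t_scores(m, y, lambda_var = 0))) < bound
  }, TRUE)
  expect_gte(sum(inside), 95)
})

test_that("correlation shrinkage adapts to the true structure and guarantees
           PD for p > n", {
  set.seed(63)
  # independent features: almost everything is noise, so shrinkage is heavy
  # and the off-diagonals of R* are suppressed toward zero
  X <- matrix(rnorm(5000 * 10), 5000, 10,
              dimnames = list(NULL, sprintf("M%06d", 1:10)))
  rownames(X) <- sprintf("S%05d", 1:5000)
  y <- rep_len(0:1, 5000)
  sh <- shrink_correlation(abundance_matrix(X, stage = "scaled"), y)
  expect_gt(sh$lambda_corr, 0.5)
  off <- sh$R_star; diag(off) <- 0
  expect_lt(max(abs(off)), 0.1)

  # genuinely correlated features at n >> p: little shrinkage is needed
  Z <- matrix(rnorm(5000 * 10), 5000, 10)
  Xc <- sqrt(0.6) * rnorm(5000) + sqrt(0.4) * Z
  colnames(Xc) <- sprintf("M%06d", 1:10)
  rownames(Xc) <- sprintf("S%05d", 1:5000)
  shc <- shrink_correlation(abundance_matrix(Xc, stage = "scaled"), y)
  expect_lt(shc$lambda_corr, 0.2)
  expect_equal(mean(shc$R_star[upper.tri(shc$R_star)]), 0.6, tolerance = 0.1)

  Xs <- matrix(rnorm(30 * 60), 30, 60,
               dimnames = list(sprintf("S%05d", 1:30), sprintf("M%06d", 1:60)))
  ys <- rep_len(0:1, 30)
  sh2 <- shrink_correlation(abundance_matrix(Xs, stage = "scaled"), ys)
  expect_gt(min(eigen(sh2$R_star, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(unname(diag(sh2$R_star)), rep(1, 60))
})

test_that("duplicated features are shrunk strictly below correlation 1", {
  set.seed(64)
  x <- rnorm(100)
  X <- cbind(x, x, matrix(rnorm(100 * 5), 100, 5))
  colnames(X) <- sprintf("M%06d", 1:7)
  rownames(X) <- sprintf("S%05d", 1:100)
  sh <- shrink_correlation(abundance_matrix(X, stage = "scaled"),
                           rep_len(0:1, 100))
  expect_lt(sh$R_star[1, 2], 1)
  expect_gt(sh$R_star[1, 2], 0.5)
})

test_that("cat equals t exactly under the identity target and is linear in t", {
  t <- c(1.5, -2, 0.3)
  expect_equal(cat_scores(t, diag(3)), t)
  expect_equal(cat_scores(numeric(3), diag(3) + 0.2 - 0.2 * diag(3)),
               numeric(3))
})

test_that("the 2x2 closed form matches the eigendecomposition route", {
  for (r in c(0.2, 0.5, 0.9)) {
    R <- matrix(c(1, r, r, 1), 2)
    t <- c(1.3, -0.4)
    # closed form: eigenvalues 1 +/- r, eigenvectors (1,1)/sqrt2, (1,-1)/sqrt2
    u1 <- c(1, 1) / sqrt(2); u2 <- c(1, -1) / sqrt(2)
    expected <- u1 * sum(u1 * t) / sqrt(1 + r) + u2 * sum(u2 * t) / sqrt(1 - r)
    expect_equal(cat_scores(t, R), expected, tolerance = 1e-12)
  }
})

test_that("the low-rank route matches the dense oracle to 1e-8", {
  for (dims in list(c(100, 30), c(40, 50))) {
    set.seed(sum(dims))
    X <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    colnames(X) <- sprintf("M%06d", seq_len(dims[2]))
    rownames(X) <- sprintf("S%05d", seq_len(dims[1]))
    X[, 1] <- X[, 2] * 0.8 + rnorm(dims[1], sd = 0.3)  # some real correlation
    y <- rep_len(0:1, dims[1])
    m <- abundance_matrix(X, stage = "scaled")
    lr <- catscore_fit(m, y, method = "lowrank")
    de <- catscore_fit(m, y, method = "dense")
    expect_equal(lr$cat_scores, de$cat_scores, tolerance = 1e-8)
    expect_equal(lr$lambda_corr, de$lambda_corr)
  }
})

test_that("cat approximately equals t on independent features", {
  sim <- simulate_metabolome(synth_config(n_samples = 2000, n_blocks = 10,
                                          block_size = 10, rho = 0,
                                          batch_shift_sd = 0, seed = 66))
  pre <- preprocess_abundance(sim$abundance, sim$metadata)
  fit <- catscore_fit(pre, sim$metadata$outcome)
  big <- abs(fit$t_scores) > 0.5  # avoid relative error blowups near zero
  rel <- abs(fit$cat_scores[big] - fit$t_scores[big]) / abs(fit$t_scores[big])
  expect_lt(max(rel), 0.05)
})

test_that("decorrelation promotes the causal member of a correlated block", {
  improved <- vapply(1:50, function(i) {
    sim <- simulate_metabolome(synth_config(n_samples = 200, n_blocks = 10,
                                            block_size = 10, rho = 0.8,
                                            n_signal_blocks = 1,
                                            beta_signal = 1.5, beta_age = 0,
                                            beta_sex = 0, seed = 800 + i))
    pre <- preprocess_abundance(sim$abundance, sim$metadata)
    fit <- catscore_fit(pre, sim$metadata$outcome)
    causal <- sim$truth$signal_features
    rank_of <- function(v) which(names(sort(-abs(v))) == causal)
    rank_of(fit$cat_scores) <= rank_of(fit$t_scores)
  }, TRUE)
  expect_gte(mean(improved), 0.8)
})

test_that("CAT ranking orders by |cat| with id tie-breaks and never imputes", {
  fit <- structure(list(cat_scores = setNames(c(0.1, -3, 2), c("A", "B", "C")),
                        t_scores = setNames(c(0.1, -3, 2), c("A", "B", "C")),
                        lambda_corr = 0.5, lambda_var = 0.5,
                        s = rep(1, 3)), class = "catscore")
  r <- rank_by_abs_cat(fit)
  expect_equal(r$rank, c(3L, 1L, 2L))
  expect_false(any(r$imputed))

  fit$cat_scores <- setNames(c(1, -1, 1), c("B", "A", "C"))
  r2 <- rank_by_abs_cat(fit)
  expect_equal(r2$rank[match(c("A", "B", "C"), r2$feature_id)], 1:3)
})
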