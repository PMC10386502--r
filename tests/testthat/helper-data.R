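# Shared fixtures: small simulated cohorts and hand-built ranking objects.

# small cohort for fast end-to-end checks
small_sim <- function(seed = 42, n = 200, n_blocks = 8, block_size = 10,
                      n_signal_blocks = 3, rho = 0.7, beta_signal = 1, ...) {
  simulate_metabolome(synth_config(n_samples = n, n_blocks = n_blocks,
                                   block_size = block_size, rho = rho,
                                   n_signal_blocks = n_signal_blocks,
                                   beta_signal = beta_signal, seed = seed,
                                   ...))
}

# a method_ranking that ranks `ranked_ids` 1..s in the given order and
# imputes the rest of `universe` at n_total
manual_ranking <- function(method, universe, ranked_ids,
                           n_total = length(universe)) {
  rank <- rep.int(n_total, length(universe))
  names(rank) <- universe
  rank[ranked_ids] <- seq_along(ranked_ids)
  imputed <- !(universe %in% ranked_ids)
  score <- ifelse(imputed, NA_real_, -rank)
  method_ranking(method, universe, score, rank, imputed, n_total)
}

# metadata table for raw matrices built by hand
manual_meta <- function(n, outcome = rep_len(c(0, 1), n),
                        batch = rep("B1", n)) {
  data.frame(sample_id = sprintf("S%05d", seq_len(n)), outcome = outcome,
             age = seq(30, 70, length.out = n),
             sex = rep_len(c("female", "male"), n), batch = batch,
             stringsAsFactors = FALSE)
}

# raw abundance matrix from a plain matrix
manual_abundance <- function(values, stage = "raw") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("S%05d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("M%06d", seq_len(ncol(values)))
  abundance_matrix(values, stage = stage)
}

# brute-force BH step-up, written independently of the implementation
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# textbook two-pass Pearson correlation
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
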