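#' Configuration for the synthetic metabolomics cohort generator
#'
#' Defines the statistical structure the generator emulates: features
#' organized in correlated blocks on the log scale, log-normal-like raw
#' intensities with additive per-batch shifts, and a binary outcome drawn
#' from a logistic model on one causal feature per signal block plus age and
#' sex effects. Defaults mirror an idiopathic-vs-other pulmonary arterial
#' hypertension case mix: mean age near 52 years, roughly 78% female, and a
#' case prevalence near 43%.
#'
#' @param n_samples number of samples.
#' @param n_blocks number of feature blocks.
#' @param block_size features per block; total features p = n_blocks *
#'   block_size.
#' @param rho within-block correlation of log intensities, in \[0, 1).
#' @param n_signal_blocks number of blocks whose first feature drives the
#'   outcome; must not exceed `n_blocks`.
#' @param beta_signal log-odds per SD of each causal feature (standardized
#'   log scale).
#' @param beta_age log-odds per year of age.
#' @param beta_sex log-odds for female vs male.
#' @param n_batches number of measurement batches.
#' @param batch_shift_sd SD of the additive per-(batch, feature) shift on
#'   the log scale.
#' @param base_log_mean location of log intensities before shifts.
#' @param target_prevalence marginal case fraction the intercept is centred
#'   on (the realized prevalence differs slightly because covariates vary).
#' @param corr_structure `"equicorrelated"` (one-factor construction) or
#'   `"ar1"` (correlation rho^|i-j| within a block).
#' @param female_frac probability a sample is female.
#' @param age_mean,age_sd mean and SD of the age distribution, truncated to
#'   \[18, 95\].
#' @param seed RNG seed; every stochastic stage of the generator derives
#'   from it.
#'
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 500, n_blocks = 20, block_size = 25,
                         rho = 0.7, n_signal_blocks = 5, beta_signal = 1,
                         beta_age = 0.02, beta_sex = 0.3, n_batches = 4,
                         batch_shift_sd = 0.3, base_log_mean = 10,
                         target_prevalence = 0.43,
                         corr_structure = c("equicorrelated", "ar1"),
                         female_frac = 0.78, age_mean = 52, age_sd = 18,
                         seed = 20230628) {
  corr_structure <- match.arg(corr_structure)
  cfg <- list(n_samples = n_samples, n_blocks = n_blocks,
              block_size = block_size, rho = rho,
              n_signal_blocks = n_signal_blocks, beta_signal = beta_signal,
              beta_age = beta_age, beta_sex = beta_sex,
              n_batches = n_batches, batch_shift_sd = batch_shift_sd,
              base_log_mean = base_log_mean,
              target_prevalence = target_prevalence,
              corr_structure = corr_structure, female_frac = female_frac,
              age_mean = age_mean, age_sd = age_sd, seed = seed)
  counts <- c("n_samples", "n_blocks", "block_size", "n_batches")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != floor(v))
      stop("`", f, "` must be a positive integer")
  }
  if (cfg$n_signal_blocks < 0 || cfg$n_signal_blocks > cfg$n_blocks)
    stop("`n_signal_blocks` must lie in [0, n_blocks]")
  if (!is.finite(cfg$rho) || cfg$rho < 0 || cfg$rho >= 1)
    stop("`rho` must lie in [0, 1)")
  if (cfg$batch_shift_sd < 0) stop("`batch_shift_sd` must be >= 0")
  if (cfg$target_prevalence <= 0 || cfg$target_prevalence >= 1)
    stop("`target_prevalence` must lie in (0, 1)")
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate a block-correlated metabolomics cohort
#'
#' Draws log-scale intensities with the configured block-correlation
#' structure, adds per-(batch, feature) shifts and exponentiates to strictly
#' positive raw intensities, then draws age, sex and a logistic outcome
#' driven by the first feature of each signal block (standardized log
#' scale). The causal feature ids are returned so recovery can be scored.
#'
#' For the equicorrelated structure each block feature is
#' `sqrt(rho) * z_block + sqrt(1 - rho) * e`, giving pairwise correlation
#' exactly `rho` within a block and independence across blocks.
#'
#' @param config a [synth_config()].
#' @return list with elements `abundance` (a raw-stage [abundance_matrix()]),
#'   `metadata` (data.frame: sample_id, outcome, age, sex, batch) and
#'   `truth` (list: `signal_features`, `config`, `intercept`).
#' @export
simulate_metabolome <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  n <- config$n_samples
  p <- config$n_blocks * config$block_size
  set.seed(config$seed)

  L <- matrix(0, n, p)
  bs <- config$block_size
  rho <- config$rho
  if (config$corr_structure == "equicorrelated") {
    for (b in seq_len(config$n_blocks)) {
      z <- rnorm(n)
      E <- matrix(rnorm(n * bs), n, bs)
      L[, (b - 1L) * bs + seq_len(bs)] <- sqrt(rho) * z + sqrt(1 - rho) * E
    }
  } else { # AR(1) within block: corr rho^|i-j|
    S <- rho^abs(outer(seq_len(bs), seq_len(bs), "-"))
    R <- chol(S)
    for (b in seq_len(config$n_blocks)) {
      E <- matrix(rnorm(n * bs), n, bs)
      L[, (b - 1L) * bs + seq_len(bs)] <- E %*% R
    }
  }
  feature_ids <- sprintf("M%06d", seq_len(p))
  sample_ids <- sprintf("S%05d", seq_len(n))

  batch <- sample(rep_len(seq_len(config$n_batches), n))
  shift <- matrix(rnorm(config$n_batches * p, sd = config$batch_shift_sd),
                  config$n_batches, p)
  raw <- exp(config$base_log_mean + L + shift[batch, , drop = FALSE])
  dimnames(raw) <- list(sample_ids, feature_ids)

  age <- rnorm(n, config$age_mean, config$age_sd)
  while (any(bad <- age < 18 | age > 95))
    age[bad] <- rnorm(sum(bad), config$age_mean, config$age_sd)
  female <- rbinom(n, 1, config$female_frac)

  signal_idx <- if (config$n_signal_blocks > 0)
    (seq_len(config$n_signal_blocks) - 1L) * bs + 1L else integer(0)
  eta0 <- config$beta_age * age + config$beta_sex * female
  if (length(signal_idx)) {
    Z <- scale(L[, signal_idx, drop = FALSE])
    eta0 <- eta0 + config$beta_signal * rowSums(Z)
  }
  intercept <- qlogis(config$target_prevalence) -
    config$beta_age * config$age_mean - config$beta_sex * config$female_frac
  outcome <- rbinom(n, 1, plogis(intercept + eta0))

  meta <- data.frame(sample_id = sample_ids, outcome = outcome, age = age,
                     sex = ifelse(female == 1, "female", "male"),
                     batch = paste0("B", batch), stringsAsFactors = FALSE)
  list(abundance = abundance_matrix(raw, stage = "raw"),
       metadata = meta,
       truth = list(signal_features = feature_ids[signal_idx],
                    intercept = intercept, config = config))
}

#' Write a simulated dataset to disk
#'
#' Emits the generator's on-disk dialect: `abundance.tsv` (first column
#' `sample_id`, then one column per feature), `phenotype.tsv` (sample_id,
#' outcome, age, sex, batch), and `truth.json` (causal feature ids plus a
#' config echo).
#'
#' @param sim result of [simulate_metabolome()].
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab_path <- file.path(dir, "abundance.tsv")
  ph_path <- file.path(dir, "phenotype.tsv")
  tr_path <- file.path(dir, "truth.json")
  ab <- data.frame(sample_id = rownames(sim$abundance),
                   as.data.frame(unclass(sim$abundance)),
                   check.names = FALSE)
  write.table(ab, ab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$metadata, ph_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(signal_features = sim$truth$signal_features,
         intercept = sim$truth$intercept,
         config = unclass(cfg)),
    tr_path, auto_unbox = TRUE, digits = NA)
  invisible(c(abundance = ab_path, phenotype = ph_path, truth = tr_path))
}

#' Read an abundance TSV written by [write_synthetic_dataset()]
#' @param path abundance TSV path.
#' @param stage stage label to assign (the file stores raw intensities by
#'   default).
#' @return an [abundance_matrix()].
#' @export
read_abundance_tsv <- function(path, stage = "raw") {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  abundance_matrix(m, stage = stage)
}

#' Read a phenotype TSV written by [write_synthetic_dataset()]
#' @param path phenotype TSV path.
#' @return validated metadata data.frame.
#' @export
read_phenotype_tsv <- function(path) {
  validate_metadata(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}
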