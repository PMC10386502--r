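#' Log-transform raw intensities
#'
#' First preprocessing step: elementwise natural log. Requires a raw-stage
#' matrix of strictly positive intensities; a non-positive value aborts with
#' the offending feature named, since it indicates an upstream extraction
#' problem rather than something to silently impute.
#'
#' @param m raw-stage [abundance_matrix()].
#' @return logged-stage `abundance_matrix`.
#' @export
log_transform <- function(m) {
  if (abundance_stage(m) != "raw")
    stop("log_transform expects stage 'raw', got '", abundance_stage(m), "'")
  bad <- colSums(m <= 0 | !is.finite(m)) > 0
  if (any(bad))
    stop("non-positive or non-finite intensities in feature(s): ",
         paste(head(colnames(m)[bad], 5), collapse = ", "))
  set_stage(m, log(unclass(m)), "logged")
}

#' Per-batch median/MAD normalization
#'
#' Removes plate-to-plate location and scale differences: within each batch,
#' each feature is centred at its batch median and divided by its batch MAD
#' (median absolute deviation scaled by the normal-consistency constant
#' 1.4826, putting it on the SD scale). Features whose batch MAD is zero
#' fall back to the feature's global MAD with a warning; if that is also
#' zero the feature is set to zeros and flagged degenerate.
#'
#' @param m logged-stage [abundance_matrix()].
#' @param meta metadata with a `batch` label per sample (see
#'   [validate_metadata()]).
#' @param mad_consistency consistency constant multiplying the raw MAD
#'   (default 1.4826).
#' @return batch-normalized `abundance_matrix`; degenerate features are
#'   recorded in [degenerate_features()].
#' @export
batch_median_mad_normalize <- function(m, meta, mad_consistency = 1.4826) {
  if (abundance_stage(m) != "logged")
    stop("batch_median_mad_normalize expects stage 'logged', got '",
         abundance_stage(m), "'")
  meta <- validate_metadata(meta, m)
  v <- unclass(m)
  batches <- unique(meta$batch)
  deg <- attr(m, "degenerate")
  global_mad <- apply(v, 2, mad, constant = mad_consistency)
  fallback <- character(0)
  for (b in batches) {
    rows <- which(meta$batch == b)
    sub <- v[rows, , drop = FALSE]
    med <- apply(sub, 2, median)
    madv <- apply(sub, 2, mad, constant = mad_consistency)
    zero <- madv == 0
    if (any(zero)) {
      fallback <- union(fallback, colnames(m)[zero])
      madv[zero] <- global_mad[zero]
      dead <- zero & global_mad == 0
      if (any(dead)) {
        deg[dead] <- TRUE
        madv[dead] <- 1  # value is zeroed below; divisor only placates NaN
      }
    }
    v[rows, ] <- sweep(sweep(sub, 2, med, "-"), 2, madv, "/")
  }
  if (any(deg)) v[, deg] <- 0
  if (length(setdiff(fallback, colnames(m)[deg])))
    warning("zero batch MAD, used global MAD for feature(s): ",
            paste(head(setdiff(fallback, colnames(m)[deg]), 5), collapse = ", "))
  set_stage(m, v, "batch_normalized", degenerate = deg)
}

#' Scale features to zero mean and unit variance
#'
#' Final preprocessing step: each feature is centred at its sample mean and
#' divided by its sample SD (n-1 denominator). Zero-variance features are
#' set to zeros and flagged degenerate rather than dropped, keeping feature
#' indexing stable across ranking methods. Applying the operation to an
#' already-scaled matrix is a no-op up to numerical precision.
#'
#' @param m batch-normalized (or scaled) [abundance_matrix()].
#' @return scaled-stage `abundance_matrix`.
#' @export
scale_features <- function(m) {
  if (!abundance_stage(m) %in% c("batch_normalized", "scaled"))
    stop("scale_features expects stage 'batch_normalized', got '",
         abundance_stage(m), "'")
  v <- unclass(m)
  mu <- colMeans(v)
  s <- apply(v, 2, sd)
  deg <- attr(m, "degenerate") | s == 0
  s[s == 0] <- 1
  v <- sweep(sweep(v, 2, mu, "-"), 2, s, "/")
  if (any(deg)) v[, deg] <- 0
  set_stage(m, v, "scaled", degenerate = deg)
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper applying the fixed order log transform -> per-batch
#' median/MAD normalization -> feature scaling.
#'
#' @inheritParams batch_median_mad_normalize
#' @return scaled-stage [abundance_matrix()].
#' @export
preprocess_abundance <- function(m, meta, mad_consistency = 1.4826) {
  scale_features(batch_median_mad_normalize(log_transform(m), meta,
                                            mad_consistency = mad_consistency))
}
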