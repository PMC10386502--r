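#' Construct an abundance matrix
#'
#' An abundance matrix is the common currency of the pipeline: a numeric
#' samples x features matrix carrying a processing-stage label so that each
#' step can verify it receives data in the state it expects. The stage
#' progresses `raw` -> `logged` -> `batch_normalized` -> `scaled`.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to existing colnames.
#' @param stage processing stage label, one of `"raw"`, `"logged"`,
#'   `"batch_normalized"`, `"scaled"`.
#'
#' @return a numeric matrix of class `abundance_matrix` with `stage` and
#'   `degenerate` attributes (the latter a named logical flagging
#'   zero-variance features, set during normalization/scaling).
#' @export
abundance_matrix <- function(values, sample_ids = rownames(values),
                             feature_ids = colnames(values),
                             stage = c("raw", "logged", "batch_normalized", "scaled")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("sample and feature identifiers are required")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stop("identifier lengths must match matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(feature_ids)) stop("duplicated feature ids")
  if (stage != "raw" && !all(is.finite(values)))
    stop("non-finite values not allowed at stage ", stage)
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values,
            stage = stage,
            degenerate = setNames(logical(length(feature_ids)), feature_ids),
            class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d features (stage: %s)\n",
              nrow(x), ncol(x), attr(x, "stage")))
  deg <- attr(x, "degenerate")
  if (any(deg)) cat(sprintf("  degenerate features: %d\n", sum(deg)))
  invisible(x)
}

#' Processing stage of an abundance matrix
#' @param m an `abundance_matrix`.
#' @return the stage label.
#' @export
abundance_stage <- function(m) attr(m, "stage")

#' Degenerate-feature flags of an abundance matrix
#' @param m an `abundance_matrix`.
#' @return named logical vector, `TRUE` for features flagged as
#'   zero-variance during normalization or scaling.
#' @export
degenerate_features <- function(m) attr(m, "degenerate")

# internal: rebuild with same ids, new values/stage, carrying flags forward
set_stage <- function(m, values, stage, degenerate = attr(m, "degenerate")) {
  out <- abundance_matrix(values, rownames(m), colnames(m), stage = stage)
  attr(out, "degenerate") <- degenerate
  out
}

#' Validate a sample metadata table
#'
#' Checks the phenotype table that accompanies an abundance matrix:
#' `sample_id`, binary `outcome` (1 = case, 0 = control), `age` in years,
#' `sex`, and `batch` label. Every sample in the abundance matrix must be
#' present; the returned table is reordered to match the matrix rows.
#'
#' @param meta data.frame with columns `sample_id`, `outcome`, `age`, `sex`,
#'   `batch`.
#' @param m optional `abundance_matrix` to align against.
#' @return the validated (and, if `m` is given, reordered) data.frame.
#' @export
validate_metadata <- function(meta, m = NULL) {
  req <- c("sample_id", "outcome", "age", "sex", "batch")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (!all(meta$outcome %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (any(!is.finite(meta$age)) || any(meta$age <= 0 | meta$age >= 120))
    stop("age must lie in (0, 120)")
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample ids in metadata")
  if (!is.null(m)) {
    idx <- match(rownames(m), meta$sample_id)
    if (anyNA(idx))
      stop("samples absent from metadata: ",
           paste(head(rownames(m)[is.na(idx)], 5), collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}
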