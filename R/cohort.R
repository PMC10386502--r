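# Cohort-characteristics reporting: the descriptive table accompanying the
# analysis (per-group n, mean/SD for continuous variables, count/percentage
# for categorical levels) with Welch t and chi-square between-group tests,
# plus the summary-statistics arithmetic needed to pool subgroup rows.

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' computed directly from subgroup means, SDs and sizes (no raw data
#' needed).
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0))
    stop("SDs must be nonnegative and not both zero")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a 2 x c contingency table
#'
#' Without continuity correction, df = c - 1.
#'
#' @param counts 2 x c matrix of nonnegative counts (groups in rows,
#'   category levels in columns).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("expected a 2 x c table")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("empty row or column margin")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Pooled mean from subgroup summaries
#' @param means subgroup means.
#' @param ns subgroup sizes.
#' @return the n-weighted mean.
#' @export
pooled_mean <- function(means, ns) sum(means * ns) / sum(ns)

#' Pooled SD from subgroup summaries
#'
#' Combined-variance identity: within-group sums of squares plus
#' between-group dispersion around the pooled mean, over N - 1.
#'
#' @param means,sds,ns subgroup summaries.
#' @return the pooled SD.
#' @export
pooled_sd <- function(means, sds, ns) {
  mu <- pooled_mean(means, ns)
  sqrt((sum((ns - 1) * sds^2) + sum(ns * (means - mu)^2)) / (sum(ns) - 1))
}

#' Cohort characteristics table
#'
#' Per-variable summaries for all samples and for each outcome group, with
#' between-group p-values: Welch t for continuous variables, Pearson
#' chi-square (no continuity correction) for categorical ones. Samples
#' missing a variable are excluded from that variable's row with a message.
#'
#' @param meta metadata (see [validate_metadata()]).
#' @param continuous names of continuous columns (default `"age"`).
#' @param categorical names of categorical columns (default `"sex"`).
#' @return data.frame of class `cohort_table`: one row per continuous
#'   variable or categorical level, with per-group sample sizes, means/SDs
#'   (continuous rows), counts/percentages (categorical rows) and
#'   `p_value`.
#' @export
cohort_summary <- function(meta, continuous = "age", categorical = "sex") {
  meta <- validate_metadata(meta)
  grp <- list(all = rep(TRUE, nrow(meta)), case = meta$outcome == 1,
              control = meta$outcome == 0)
  rows <- list()
  for (v in continuous) {
    x <- meta[[v]]
    if (is.null(x)) stop("missing continuous column: ", v)
    ok <- is.finite(x)
    if (any(!ok)) message(sum(!ok), " samples missing '", v, "' excluded")
    w <- welch_t(mean(x[ok & grp$case]), sd(x[ok & grp$case]), sum(ok & grp$case),
                 mean(x[ok & grp$control]), sd(x[ok & grp$control]),
                 sum(ok & grp$control))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = NA_character_,
      n_all = sum(ok), n_case = sum(ok & grp$case),
      n_control = sum(ok & grp$control),
      mean_all = mean(x[ok]), sd_all = sd(x[ok]),
      mean_case = mean(x[ok & grp$case]), sd_case = sd(x[ok & grp$case]),
      mean_control = mean(x[ok & grp$control]),
      sd_control = sd(x[ok & grp$control]),
      count_all = NA_integer_, pct_all = NA_real_,
      count_case = NA_integer_, pct_case = NA_real_,
      count_control = NA_integer_, pct_control = NA_real_,
      p_value = w$p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- meta[[v]]
    if (is.null(x)) stop("missing categorical column: ", v)
    ok <- !is.na(x)
    if (any(!ok)) message(sum(!ok), " samples missing '", v, "' excluded")
    lev <- sort(unique(x[ok]))
    tab <- rbind(case = vapply(lev, function(l) sum(ok & grp$case & x == l), 0),
                 control = vapply(lev, function(l) sum(ok & grp$control & x == l), 0))
    p <- if (length(lev) > 1) chi_square(tab)$p else NA_real_
    for (l in lev) {
      ca <- sum(ok & grp$case & x == l); co <- sum(ok & grp$control & x == l)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = l,
        n_all = sum(ok), n_case = sum(ok & grp$case),
        n_control = sum(ok & grp$control),
        mean_all = NA_real_, sd_all = NA_real_, mean_case = NA_real_,
        sd_case = NA_real_, mean_control = NA_real_, sd_control = NA_real_,
        count_all = ca + co, pct_all = 100 * (ca + co) / sum(ok),
        count_case = ca, pct_case = 100 * ca / sum(ok & grp$case),
        count_control = co, pct_control = 100 * co / sum(ok & grp$control),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("cohort_table", "data.frame"))
}

#' Write a cohort table to TSV
#' @param table a [cohort_summary()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cohort_tsv <- function(table, path) {
  out <- as.data.frame(table)
  for (j in seq_along(out))  # full precision so the TSV round-trips exactly
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.17g", out[[j]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a cohort table written by [write_cohort_tsv()]
#' @param path TSV path.
#' @return the `cohort_table` data.frame.
#' @export
read_cohort_tsv <- function(path) {
  structure(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, na.strings = "NA"),
            class = c("cohort_table", "data.frame"))
}
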