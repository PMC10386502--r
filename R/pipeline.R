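# End-to-end orchestration: preprocess -> seven rankings (bonferroni, fdr,
# lasso, elastic_net, random_forest, sda, xgboost) -> aggregation ->
# per-method convergence diagnostics -> cohort table, with every artifact
# written to a run directory plus a machine-readable manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the full run: preprocessing constants,
#' per-method hyperparameters, top-k and focus sizes, convergence
#' thresholds, and the master seed from which each stochastic stage derives
#' its own. The Bonferroni and FDR rankings are tabulated as two methods,
#' so a full run produces seven ranking columns from six approaches.
#'
#' @param seed master seed; stage seeds are derived as small offsets.
#' @param methods which ranking methods to run.
#' @param mad_consistency MAD consistency constant (see
#'   [batch_median_mad_normalize()]).
#' @param folds cross-validation folds for the penalized fits.
#' @param alpha_grid elastic-net mixing grid.
#' @param nlambda,lambda.min.ratio penalized lambda-grid shape.
#' @param adjust_covariates unpenalized age/sex columns in the penalized
#'   fits?
#' @param mtry_grid,nodesize_grid,n_trees forest tuning grids and size;
#'   `NULL` `mtry_grid` means the default sqrt(p), p/10, p/3.
#' @param forest_selection `"off"` or `"on"` (minimal-depth selection gate).
#' @param xgb_param_grid data.frame of `max_depth`/`eta` candidates.
#' @param xgb_folds,xgb_nrounds_max,xgb_early_stopping boosting tuning
#'   controls.
#' @param k top-list size for convergence diagnostics (default 50).
#' @param n_focus integrated-rank focus window (default 500).
#' @param high_threshold,rule_threshold convergence thresholds (see
#'   [fraction_correlated()] and [classify_method()]).
#' @param continuous,categorical cohort-table variables.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            methods = c("bonferroni", "fdr", "lasso",
                                        "elastic_net", "random_forest",
                                        "sda", "xgboost"),
                            mad_consistency = 1.4826,
                            folds = 10,
                            alpha_grid = seq(0.1, 1, by = 0.1),
                            nlambda = 100, lambda.min.ratio = 1e-3,
                            adjust_covariates = TRUE,
                            mtry_grid = NULL, nodesize_grid = c(5, 15, 50),
                            n_trees = 500,
                            forest_selection = "off",
                            xgb_param_grid = expand.grid(max_depth = c(2, 4, 6),
                                                         eta = c(0.05, 0.1, 0.3)),
                            xgb_folds = 5, xgb_nrounds_max = 200,
                            xgb_early_stopping = 20,
                            k = 50, n_focus = 500,
                            high_threshold = 0.4, rule_threshold = 0.5,
                            continuous = "age", categorical = "sex") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# internal: run one stage with context on failure
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full multi-method prioritization pipeline
#'
#' Preprocesses the abundance matrix, fits every configured ranking method,
#' aggregates the ranks, computes per-method convergence diagnostics and
#' the cohort table, and writes all artifacts (ranking TSVs, aggregate TSV,
#' convergence summaries, cohort TSV, JSON manifest and log) to `out_dir`.
#' Reruns with an identical configuration and inputs are byte-identical.
#'
#' @param abundance raw-stage [abundance_matrix()].
#' @param metadata sample metadata (see [validate_metadata()]).
#' @param config a [pipeline_config()].
#' @param out_dir run directory, created if needed; `NULL` skips writing.
#' @return invisibly, a list: `preprocessed`, `rankings` (named list of
#'   [method_ranking()]), `aggregate`, `focus`, `convergence` (named list of
#'   [convergence_summary()]), `cohort`, `manifest`.
#' @export
run_pipeline <- function(abundance, metadata, config = pipeline_config(),
                         out_dir = NULL) {
  metadata <- validate_metadata(metadata, abundance)
  n_total <- ncol(abundance)
  seed <- as.integer(config$seed)

  pre <- run_stage("preprocess",
                   preprocess_abundance(abundance, metadata,
                                        mad_consistency = config$mad_consistency))
  rankings <- list()
  if (any(c("bonferroni", "fdr") %in% config$methods)) {
    uni <- run_stage("univariate", rank_univariate(pre, metadata, n_total))
    if ("bonferroni" %in% config$methods) rankings$bonferroni <- uni$bonferroni
    if ("fdr" %in% config$methods) rankings$fdr <- uni$fdr
  }
  if ("lasso" %in% config$methods) {
    fit <- run_stage("lasso",
                     fit_lasso_cv(pre, metadata, folds = config$folds,
                                  seed = seed + 1L, nlambda = config$nlambda,
                                  lambda.min.ratio = config$lambda.min.ratio,
                                  adjust_covariates = config$adjust_covariates))
    rankings$lasso <- rank_by_abs_coefficients(fit$coefficients, "lasso",
                                               n_total)
  }
  if ("elastic_net" %in% config$methods) {
    fit <- run_stage("elastic_net",
                     fit_elastic_net_cv(pre, metadata,
                                        alpha_grid = config$alpha_grid,
                                        folds = config$folds, seed = seed + 2L,
                                        nlambda = config$nlambda,
                                        lambda.min.ratio = config$lambda.min.ratio,
                                        adjust_covariates = config$adjust_covariates))
    rankings$elastic_net <- rank_by_abs_coefficients(fit$coefficients,
                                                     "elastic_net", n_total)
  }
  if ("random_forest" %in% config$methods) {
    fm <- run_stage("random_forest",
                    tune_and_fit_forest(pre, metadata$outcome,
                                        mtry_grid = config$mtry_grid,
                                        nodesize_grid = config$nodesize_grid,
                                        n_trees = config$n_trees,
                                        seed = seed + 3L))
    rankings$random_forest <- rank_forest(minimal_depth(fm),
                                          forest_importance(fm),
                                          selection = config$forest_selection,
                                          n_total = n_total)
  }
  if ("sda" %in% config$methods) {
    cs <- run_stage("sda", catscore_fit(pre, metadata$outcome))
    rankings$sda <- rank_by_abs_cat(cs, n_total)
  }
  if ("xgboost" %in% config$methods) {
    bm <- run_stage("xgboost",
                    tune_and_fit_xgb(pre, metadata$outcome,
                                     param_grid = config$xgb_param_grid,
                                     folds = config$xgb_folds,
                                     seed = seed + 4L,
                                     nrounds_max = config$xgb_nrounds_max,
                                     early_stopping = config$xgb_early_stopping))
    rankings$xgboost <- rank_xgb_gain(bm, n_total)
  }

  aggregate <- run_stage("aggregate", aggregate_ranks(rankings, n_total))
  focus <- run_stage("focus",
                     focus_top(aggregate, min(config$n_focus, n_total)))
  convergence <- run_stage("convergence", lapply(rankings, function(r)
    convergence_summary(r, pre, k = config$k,
                        high_threshold = config$high_threshold,
                        rule_threshold = config$rule_threshold)))
  cohort <- run_stage("cohort",
                      cohort_summary(metadata, continuous = config$continuous,
                                     categorical = config$categorical))

  manifest <- list(
    n_samples = nrow(abundance), n_features = n_total, seed = seed,
    methods = names(rankings),
    files = character(0),
    convergence = lapply(convergence, function(s)
      list(pair_fraction = s$pair_fraction, participation = s$participation,
           r_range = s$r_range, label = s$label)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (nm in names(rankings)) {
      f <- file.path(out_dir, paste0("ranking_", nm, ".tsv"))
      write_ranking_tsv(rankings[[nm]], f)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "aggregate.tsv")
    write.table(aggregate, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    for (nm in names(convergence)) {
      f <- file.path(out_dir, paste0("convergence_", nm, ".tsv"))
      write.table(convergence[[nm]]$corr, f, sep = "\t", quote = FALSE)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "cohort.tsv")
    write_cohort_tsv(cohort, f)
    files <- c(files, f)
    manifest$files <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(paste("metarank", as.character(utils::packageVersion("metarank"))),
                 paste("R", paste(R.version$major, R.version$minor, sep = ".")),
                 paste("seed", seed),
                 paste("methods", paste(names(rankings), collapse = ","))),
               file.path(out_dir, "run.log"))
  }
  invisible(list(preprocessed = pre, rankings = rankings,
                 aggregate = aggregate, focus = focus,
                 convergence = convergence, cohort = cohort,
                 manifest = manifest))
}
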