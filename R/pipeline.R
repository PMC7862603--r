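#' Pipeline run configuration
#'
#' Bundles every tunable of the derivation/validation pipeline with the
#' published defaults: DEG thresholds FDR < 0.01 and |log2FC| > 1, meta
#' p < 0.01, lasso penalty 0.5 chosen from the five-point grid, score
#' maximum 50, strata cuts (10, 25, 40), and an optional 120-month
#' truncation for external validation.
#'
#' @param fdr_threshold,lfc_threshold DEG-stage cutoffs.
#' @param meta_p Meta-analysis selection threshold.
#' @param lambda Default L1 penalty.
#' @param lambda_grid Candidate penalties for validation tuning.
#' @param tune If `TRUE`, choose lambda on the internal validation half;
#'   otherwise use `lambda` as is.
#' @param score_max Score maximum.
#' @param strata_cuts Interior stratification cut points.
#' @param truncate_months Administrative censoring horizon for validation
#'   (`NULL` to disable).
#' @param train_fraction Training fraction of the training cohort.
#' @param seed Master seed; stage sub-seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fdr_threshold = 0.01, lfc_threshold = 1,
                       meta_p = 0.01, lambda = 0.5,
                       lambda_grid = c(0.01, 0.05, 0.1, 0.5, 1),
                       tune = TRUE, score_max = 50,
                       strata_cuts = c(10, 25, 40),
                       truncate_months = 120, train_fraction = 0.5,
                       seed = 1L) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, lfc_threshold >= 0,
            meta_p > 0, meta_p < 1, lambda >= 0, score_max > 0,
            length(strata_cuts) == 3, !is.unsorted(strata_cuts))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

# deterministic sub-seed per stage, kept within 32-bit integer range
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483647L
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = 12)
  # 31-ary polynomial rolling hash over the serialized config
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Derive a signature: DEG filter, meta filter, lasso training
#'
#' Runs the full derivation: (1) NB differential expression between the
#' paired tumor/normal count matrices; (2) random-effects meta-analysis of
#' median-dichotomized hazard ratios of the DEGs across the survival
#' cohorts; (3) Gene_Score binarization of the training cohort against each
#' selected gene's integrated HR; (4) lasso on the truncated-survival
#' target over a stratified training/validation split, with the penalty
#' optionally tuned on the validation half; (5) weight normalization to the
#' score maximum. The run report records gene counts after every stage.
#'
#' @param tumor,normal Count-scale [expression_matrix()] pair for the DEG
#'   stage.
#' @param cohorts List of [cohort_dataset()] survival cohorts for the meta
#'   stage.
#' @param training_cohort A [cohort_dataset()] for signature training.
#' @param config A [run_config()].
#' @return A list of class `derivation_run`: `signature`
#'   ([mps_signature()]) and `report` (stage gene counts, chosen lambda,
#'   convergence, seed, config hash).
#' @export
run_derivation <- function(tumor, normal, cohorts, training_cohort,
                           config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(seed = config$seed, config_hash = config_hash(config))
  deg <- tryCatch(
    call_degs(tumor, normal, config$fdr_threshold, config$lfc_threshold),
    error = function(e) stop("stage 'deg': ", conditionMessage(e)))
  deg_genes <- deg$gene_id[deg$is_deg]
  report$n_genes_tested <- nrow(deg)
  report$n_deg <- length(deg_genes)
  if (!length(deg_genes)) stop("stage 'deg': no differentially expressed genes")
  meta_sel <- tryCatch(
    select_prognostic(deg_genes, cohorts, config$meta_p),
    error = function(e) stop("stage 'meta': ", conditionMessage(e)))
  report$n_prognostic <- nrow(meta_sel)
  if (!nrow(meta_sel)) stop("stage 'meta': no prognostic genes selected")
  halves <- split_train_validation(training_cohort,
                                   fraction = config$train_fraction,
                                   seed = stage_seed(config$seed, 3L))
  make_design <- function(co) {
    pseudo <- mps_signature(meta_sel$gene_id,
                            ifelse(meta_sel$integrated_hr > 1, "HIGH", "LOW"),
                            rep(1, nrow(meta_sel)),
                            score_max = nrow(meta_sel))
    clin <- filter_positive_survival(co$clinical, quiet = TRUE)
    expr <- co$expression[, clin$sample_id, drop = FALSE]
    attr(expr, "scale") <- attr(co$expression, "scale")
    class(expr) <- class(co$expression)
    list(X = t(binarize_cohort(expr, pseudo)),
         y = build_target(clin$time))
  }
  tr <- make_design(halves$training)
  lambda <- config$lambda
  tuning <- NULL
  if (config$tune && !is.null(halves$validation)) {
    va <- make_design(halves$validation)
    tuning <- tune_lambda(tr$X, tr$y, va$X, va$y, grid = config$lambda_grid)
    lambda <- tuning$lambda
  }
  fit <- tryCatch(lasso_fit(tr$X, tr$y, lambda = lambda),
                  error = function(e) stop("stage 'train': ",
                                           conditionMessage(e)))
  sig <- tryCatch(extract_signature(fit$beta, meta_sel,
                                    score_max = config$score_max),
                  error = function(e) stop("stage 'train': ",
                                           conditionMessage(e)))
  report$lambda <- lambda
  report$lambda_mse <- tuning$mse
  report$lasso_converged <- fit$converged
  report$lasso_iterations <- fit$iterations
  report$n_signature <- nrow(sig)
  structure(list(signature = sig, report = report,
                 deg = deg, meta = meta_sel),
            class = "derivation_run")
}

#' Validate a signature on an independent cohort
#'
#' Scores the cohort with the signature and runs the stratified survival
#' battery ([evaluate_strata()]), honouring the configured truncation
#' horizon. Works for any declared endpoint (RFS, DFS or OS).
#'
#' @param signature An [mps_signature()].
#' @param cohort A [cohort_dataset()]; all signature genes must be present.
#' @param config A [run_config()].
#' @param covariates Optional covariate column names for the multivariate
#'   model.
#' @return A list of class `validation_run`: `scores`, `report` (an
#'   [evaluate_strata()] `strata_report`), `endpoint`, `config_hash`,
#'   `seed`.
#' @export
run_validation <- function(signature, cohort, config = run_config(),
                           covariates = NULL) {
  stopifnot(inherits(config, "run_config"))
  clin <- filter_positive_survival(cohort$clinical, quiet = TRUE)
  scores <- score_cohort(cohort, signature)
  report <- evaluate_strata(scores, clin, covariates = covariates,
                            truncate_months = config$truncate_months)
  structure(list(scores = scores, report = report,
                 endpoint = attr(cohort$clinical, "endpoint"),
                 config_hash = config_hash(config), seed = config$seed),
            class = "validation_run")
}
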