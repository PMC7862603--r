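#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. The defaults describe a desk-scale version of the study design
#' the pipeline targets: a paired tumor/normal count experiment with a
#' minority of genes truly differential, and several survival cohorts in
#' which a handful of genes carry a hazard that depends on above/below-median
#' expression status.
#'
#' @param n_genes Number of genes simulated.
#' @param n_planted_deg Genes with a planted tumor/normal fold-change.
#' @param n_planted_prognostic Genes with a planted median-status hazard
#'   effect.
#' @param log2fc_planted Planted differential effect, log2 units.
#' @param beta_planted Planted log hazard ratio of above- vs below-median
#'   status (natural log).
#' @param direction_planted Sign pattern for planted effects: `"alternating"`
#'   (default), `"up"` or `"down"`. For prognostic genes a positive sign
#'   means above-median expression is harmful.
#' @param n_cohorts Number of survival cohorts.
#' @param n_per_cohort Patients per survival cohort.
#' @param n_tumor,n_normal Samples per arm of the paired count experiment.
#' @param depth Expected library size (total counts per sample).
#' @param baseline_hazard Baseline event rate, events per month.
#' @param censor_rate Target fraction of censored patients, in [0, 1);
#'   achieved by independent exponential censoring whose rate is solved
#'   numerically.
#' @param nb_dispersion Negative-binomial dispersion of simulated counts.
#' @param cohort_scale_sd SD of the per-gene, per-cohort additive platform
#'   shift on the log-expression scale.
#' @param expr_sd Within-cohort biological SD of log expression.
#' @param continuous_effect If `TRUE`, the planted hazard acts on the
#'   standardized continuous log expression instead of the median status
#'   (robustness-testing mode).
#' @param covariates If `TRUE`, cohorts carry `stage` (ordinal 1-4) and
#'   `sex` covariates with log-hazard effects `stage_log_hr` per stage step
#'   and `sex_log_hr` for males.
#' @param stage_log_hr,sex_log_hr Covariate log-hazard effects.
#' @param seed Default seed used when none is passed to the generators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_planted_deg = 50,
                       n_planted_prognostic = 20,
                       log2fc_planted = 2,
                       beta_planted = 0.7,
                       direction_planted = c("alternating", "up", "down"),
                       n_cohorts = 4,
                       n_per_cohort = 150,
                       n_tumor = 40,
                       n_normal = 40,
                       depth = 1e5,
                       baseline_hazard = 0.02,
                       censor_rate = 0.5,
                       nb_dispersion = 0.2,
                       cohort_scale_sd = 1,
                       expr_sd = 1,
                       continuous_effect = FALSE,
                       covariates = TRUE,
                       stage_log_hr = 0.35,
                       sex_log_hr = 0.1,
                       seed = 1L) {
  direction_planted <- match.arg(direction_planted)
  cfg <- as.list(environment())
  if (cfg$n_planted_deg > cfg$n_genes || cfg$n_planted_prognostic > cfg$n_genes)
    stop("planted gene counts cannot exceed n_genes")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (!is.finite(cfg$beta_planted))
    stop("beta_planted must be finite")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

planted_signs <- function(n, pattern) {
  switch(pattern,
         alternating = rep_len(c(1, -1), n),
         up = rep(1, n),
         down = rep(-1, n))
}

#' Simulate a paired tumor/normal count experiment
#'
#' Draws negative-binomial read counts for two arms sharing per-gene
#' baseline expression. Planted differential genes have their tumor-arm
#' mean multiplied by `2^(sign * log2fc_planted)`; all other genes follow
#' the same law in both arms. Gene baselines are log-normal and samples
#' share the configured expected depth, so library sizes are realistic but
#' exchangeable.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`. All randomness in
#'   the function flows from it.
#' @return A list with `tumor` and `normal` ([expression_matrix()] objects,
#'   count scale) and `truth`, a data.frame of planted genes with their
#'   signed log2 fold-changes.
#' @export
simulate_paired_counts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  G <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(G))
  # relative gene abundances, log-normal, scaled to the target depth
  rel <- exp(stats::rnorm(G, mean = 0, sd = 1.5))
  rel <- rel / sum(rel)
  mu0 <- rel * config$depth
  signs <- planted_signs(config$n_planted_deg, config$direction_planted)
  planted <- if (config$n_planted_deg > 0) seq_len(config$n_planted_deg) else integer(0)
  mu_t <- mu0
  if (length(planted))
    mu_t[planted] <- mu0[planted] * 2^(signs * config$log2fc_planted)
  draw <- function(mu, n, prefix) {
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    m <- matrix(stats::rnbinom(G * n, mu = rep(mu, n), size = size),
                nrow = G, ncol = n,
                dimnames = list(genes, paste0(prefix, seq_len(n))))
    storage.mode(m) <- "double"
    m
  }
  tumor <- expression_matrix(draw(mu_t, config$n_tumor, "T"), "count")
  normal <- expression_matrix(draw(mu0, config$n_normal, "N"), "count")
  truth <- data.frame(gene_id = genes[planted],
                      log2fc = if (length(planted)) signs * config$log2fc_planted else numeric(0),
                      stringsAsFactors = FALSE)
  list(tumor = tumor, normal = normal, truth = truth)
}

# Solve the exponential censoring rate c so that the expected censored
# fraction mean_i c / (c + h_i) matches the target, given per-patient
# event hazards h_i.
censor_rate_solve <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(cc) mean(cc / (cc + hazards)) - target
  stats::uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12)$root
}

#' Simulate multi-cohort survival data with planted prognostic genes
#'
#' Each cohort carries log-scale expression for `n_genes` genes: a shared
#' per-gene baseline, a per-gene-per-cohort platform shift (N(0,
#' `cohort_scale_sd`^2)) emulating different array/sequencing platforms, and
#' within-cohort noise. The first `n_planted_prognostic` genes drive an
#' exponential event hazard through their above/below-median status:
#' hazard_i = baseline_hazard * exp(sum_g beta_planted * sign_g *
#' (status_gi - 1/2)) (centred so the cohort-median patient sits near the
#' baseline rate), times optional stage/sex covariate effects. Censoring is
#' independent exponential with its rate solved to hit `censor_rate`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `cohorts` (list of [cohort_dataset()]) and `truth`
#'   (data.frame: planted gene, sign, log hazard ratio).
#' @export
simulate_survival_cohorts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  G <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(G))
  base <- stats::rnorm(G, mean = 6, sd = 1.2)
  P <- config$n_planted_prognostic
  signs <- planted_signs(P, config$direction_planted)
  cohorts <- vector("list", config$n_cohorts)
  for (c_idx in seq_len(config$n_cohorts)) {
    n <- config$n_per_cohort
    shift <- stats::rnorm(G, 0, config$cohort_scale_sd)
    expr <- base + shift +
      matrix(stats::rnorm(G * n, 0, config$expr_sd), G, n)
    dimnames(expr) <- list(genes,
                           sprintf("C%d_s%03d", c_idx, seq_len(n)))
    lp <- rep(0, n)
    if (P > 0) {
      for (g in seq_len(P)) {
        if (config$continuous_effect) {
          z <- (expr[g, ] - mean(expr[g, ])) / stats::sd(expr[g, ])
          lp <- lp + config$beta_planted * signs[g] * z / 2
        } else {
          status <- as.numeric(expr[g, ] > stats::median(expr[g, ]))
          lp <- lp + config$beta_planted * signs[g] * (status - 0.5)
        }
      }
    }
    covs <- NULL
    if (config$covariates) {
      stage <- sample(1:4, n, replace = TRUE, prob = c(0.18, 0.38, 0.3, 0.14))
      sex <- sample(c("F", "M"), n, replace = TRUE)
      lp <- lp + config$stage_log_hr * (stage - mean(1:4)) +
        config$sex_log_hr * (sex == "M")
      covs <- data.frame(stage = stage, sex = sex, stringsAsFactors = FALSE)
    }
    hazard <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = hazard)
    c_rate <- censor_rate_solve(hazard, config$censor_rate)
    t_cens <- if (c_rate > 0) stats::rexp(n, rate = c_rate) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clin <- clinical_table(colnames(expr), time, event, covariates = covs,
                           endpoint = "RFS")
    cohorts[[c_idx]] <- cohort_dataset(sprintf("sim_cohort_%d", c_idx),
                                       expression_matrix(expr, "log"),
                                       clin, quiet = TRUE)
  }
  truth <- data.frame(gene_id = genes[seq_len(P)],
                      sign = signs,
                      log_hr = signs * config$beta_planted,
                      stringsAsFactors = FALSE)
  list(cohorts = cohorts, truth = truth)
}
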