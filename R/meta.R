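#' Dichotomize expression at the cohort median
#'
#' Splits one gene's expression values in one cohort into HIGH (strictly
#' above the median) and LOW (at or below it). The tie-at-median convention
#' guarantees the HIGH group is strictly above the cutoff. A constant
#' vector cannot be split and is flagged degenerate.
#'
#' @param values Numeric vector of one gene's expression across a cohort.
#' @return Integer vector (1 = HIGH, 0 = LOW) with attribute `degenerate`
#'   (logical) and `cutoff` (the median); degenerate input returns all-LOW
#'   with `degenerate = TRUE`.
#' @export
dichotomize_at_median <- function(values) {
  if (anyNA(values)) stop("missing values; exclude the gene in this cohort")
  med <- stats::median(values)
  status <- as.integer(values > med)
  degenerate <- length(unique(values)) < 2L || all(status == 0L) ||
    all(status == 1L)
  structure(status, degenerate = degenerate, cutoff = med)
}

# Breslow-ties partial likelihood pieces for a bank of binary covariates
# sharing one (time, event) outcome. Returns per-unique-event-time totals:
# d (events), r (at risk) and, per gene, d1 and r1 (events / at risk in the
# HIGH group). Rows of `status` are genes.
cox_binary_prep <- function(status, time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  status <- status[, ord, drop = FALSE]
  et <- unique(time[event == 1])
  if (!length(et)) stop("no events in cohort")
  # index of first subject still at risk at each event time
  first_at_risk <- findInterval(et, time, left.open = TRUE) + 1L
  n <- length(time)
  # suffix sums of status give r1 (HIGH subjects at risk) at each event time
  lower <- 1 * outer(seq_len(n), seq_len(n), ">=")
  suff <- status %*% lower
  r1 <- suff[, first_at_risk, drop = FALSE]
  r <- (n:1)[first_at_risk]
  ev_rows <- which(event == 1)
  f <- factor(time[ev_rows], levels = et)
  d <- as.vector(table(f))
  d1 <- t(rowsum(t(status[, ev_rows, drop = FALSE]), f))
  list(et = et, d = d, r = r, r1 = r1, d1 = d1)
}

# Newton-Raphson on the Breslow partial likelihood for each row of a
# binary status matrix; vectorized across genes.
cox_binary_fit <- function(status, time, event, tol = 1e-8, max_iter = 50L) {
  pr <- cox_binary_prep(status, time, event)
  G <- nrow(status)
  beta <- rep(0, G)
  s1 <- rowSums(pr$d1)
  conv <- rep(FALSE, G)
  for (it in seq_len(max_iter)) {
    eb <- exp(beta)
    r1e <- pr$r1 * eb                       # genes x event-times
    r0 <- sweep(-pr$r1, 2L, pr$r, "+")      # r - r1
    denom <- r0 + r1e
    mu <- sweep(r1e / denom, 2L, pr$d, "*")
    U <- s1 - rowSums(mu)
    I <- rowSums(sweep(r1e * r0 / denom^2, 2L, pr$d, "*"))
    step <- ifelse(I > 1e-12, U / I, 0)
    step <- pmax(pmin(step, 2), -2)
    beta <- beta + step
    conv <- abs(step) < tol
    if (all(conv)) break
  }
  eb <- exp(beta)
  r0 <- sweep(-pr$r1, 2L, pr$r, "+")
  denom <- r0 + pr$r1 * eb
  I <- rowSums(sweep((pr$r1 * eb) * r0 / denom^2, 2L, pr$d, "*"))
  se <- ifelse(I > 1e-12, 1 / sqrt(I), NA_real_)
  converged <- conv & abs(beta) < 15 & is.finite(se)
  list(log_hr = beta, se = se, converged = converged,
       n_events = sum(event == 1))
}

#' Univariate Cox hazard ratio for a binary expression status
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) for a single
#' binary covariate by Newton-Raphson, returning the high-vs-low log hazard
#' ratio and its standard error from the observed information. A monotone
#' likelihood (all events stacked at one extreme) is flagged non-converged.
#'
#' @param status Binary vector (1 = HIGH, 0 = LOW).
#' @param time,event Survival outcome (months, 0/1 indicator).
#' @return A list: `log_hr`, `se`, `n_events`, `converged`.
#' @export
cohort_hr <- function(status, time, event) {
  status <- as.numeric(status)
  if (length(unique(status)) < 2L)
    stop("both status levels must be present")
  if (sum(event) < 1L) stop("no events in cohort")
  f <- cox_binary_fit(matrix(status, nrow = 1), time, event)
  list(log_hr = f$log_hr[1], se = f$se[1], n_events = f$n_events,
       converged = f$converged[1])
}

#' DerSimonian-Laird random-effects pooling of log hazard ratios
#'
#' Pools per-cohort estimates with inverse-variance fixed-effect weights to
#' form Cochran's Q, estimates the between-cohort variance tau^2 by the
#' method of moments (truncated at zero), re-weights by 1/(se^2 + tau^2),
#' and tests the pooled log hazard ratio against zero with a normal
#' approximation.
#'
#' @param log_hr Per-cohort log hazard ratios.
#' @param se Their standard errors (positive).
#' @return A list: `pooled_log_hr`, `pooled_se`, `tau2`, `q_stat`,
#'   `p_value`, `integrated_hr` (= exp(pooled)), `k` (number of cohorts).
#' @export
pool_random_effects <- function(log_hr, se) {
  if (!length(log_hr)) stop("no cohort estimates to pool")
  if (length(se) != length(log_hr) || any(se <= 0) || any(!is.finite(log_hr)))
    stop("invalid estimates: need finite log_hr and positive se")
  k <- length(log_hr)
  w <- 1 / se^2
  theta_fe <- sum(w * log_hr) / sum(w)
  q <- sum(w * (log_hr - theta_fe)^2)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  w_re <- 1 / (se^2 + tau2)
  pooled <- sum(w_re * log_hr) / sum(w_re)
  pooled_se <- sqrt(1 / sum(w_re))
  p <- 2 * stats::pnorm(-abs(pooled / pooled_se))
  list(pooled_log_hr = pooled, pooled_se = pooled_se, tau2 = tau2,
       q_stat = q, p_value = p, integrated_hr = exp(pooled), k = k)
}

#' Meta-analyse median-dichotomized hazard ratios across cohorts
#'
#' For every candidate gene and every cohort: dichotomize expression at the
#' within-cohort median, fit the univariate Cox model, and pool the
#' resulting log hazard ratios with [pool_random_effects()]. Genes that are
#' degenerate or non-converged in a cohort are pooled over the remaining
#' cohorts; genes usable in no cohort are reported with `k = 0` and `NA`
#' estimates.
#'
#' @param genes Character vector of candidate gene IDs (e.g. the DEG list).
#' @param cohorts List of [cohort_dataset()] objects.
#' @return A data.frame, one row per gene: `gene_id`, `pooled_log_hr`,
#'   `pooled_se`, `tau2`, `q_stat`, `p_value`, `integrated_hr`, `k_cohorts`.
#' @export
meta_analyse_genes <- function(genes, cohorts) {
  stopifnot(length(cohorts) >= 1)
  per_cohort <- vector("list", length(cohorts))
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    stopifnot(inherits(co, "cohort_dataset"))
    present <- intersect(genes, rownames(co$expression))
    if (!length(present)) next
    expr <- unclass(co$expression)[present, , drop = FALSE]
    # genes with any missing value are excluded from this cohort: a median
    # over partial data would distort the cutoff
    usable <- rowSums(is.na(expr)) == 0
    meds <- apply(expr, 1L, stats::median)
    status <- (expr > meds) * 1
    non_deg <- usable & rowSums(status) > 0 & rowSums(status) < ncol(status)
    if (!any(non_deg)) next
    fit <- cox_binary_fit(status[non_deg, , drop = FALSE],
                          co$clinical$time, co$clinical$event)
    keep <- fit$converged
    per_cohort[[ci]] <- data.frame(gene_id = present[non_deg][keep],
                                   log_hr = fit$log_hr[keep],
                                   se = fit$se[keep],
                                   stringsAsFactors = FALSE)
  }
  est <- do.call(rbind, per_cohort)
  out <- data.frame(gene_id = genes, pooled_log_hr = NA_real_,
                    pooled_se = NA_real_, tau2 = NA_real_,
                    q_stat = NA_real_, p_value = NA_real_,
                    integrated_hr = NA_real_, k_cohorts = 0L,
                    stringsAsFactors = FALSE)
  if (is.null(est) || !nrow(est)) return(out)
  # vectorized DerSimonian-Laird over all genes at once (same formulas as
  # pool_random_effects; the two are cross-checked in the test suite)
  g <- factor(est$gene_id, levels = unique(est$gene_id))
  gi <- as.integer(g)
  w <- 1 / est$se^2
  sw <- as.vector(rowsum(w, g))
  sw2 <- as.vector(rowsum(w^2, g))
  k <- as.vector(rowsum(rep(1, nrow(est)), g))
  theta_fe <- as.vector(rowsum(w * est$log_hr, g)) / sw
  q <- as.vector(rowsum(w * (est$log_hr - theta_fe[gi])^2, g))
  tau2 <- ifelse(k > 1, pmax(0, (q - (k - 1)) / (sw - sw2 / sw)), 0)
  w_re <- 1 / (est$se^2 + tau2[gi])
  sw_re <- as.vector(rowsum(w_re, g))
  pooled <- as.vector(rowsum(w_re * est$log_hr, g)) / sw_re
  pooled_se <- sqrt(1 / sw_re)
  idx <- match(levels(g), genes)
  out$pooled_log_hr[idx] <- pooled
  out$pooled_se[idx] <- pooled_se
  out$tau2[idx] <- tau2
  out$q_stat[idx] <- q
  out$p_value[idx] <- 2 * stats::pnorm(-abs(pooled / pooled_se))
  out$integrated_hr[idx] <- exp(pooled)
  out$k_cohorts[idx] <- k
  out
}

#' Second filter: select prognostic genes by random-effects meta-analysis
#'
#' Runs [meta_analyse_genes()] on the candidate list and keeps genes whose
#' pooled two-sided p-value falls below `p_threshold` (strict). The full
#' per-gene table is attached as attribute `all_results` for reporting.
#'
#' @param genes Candidate gene IDs (typically the DEG list).
#' @param cohorts List of [cohort_dataset()] survival cohorts.
#' @param p_threshold Strict selection threshold (default 0.01).
#' @return The selected subset of the meta-analysis table, each row carrying
#'   the gene's `integrated_hr` used later for Gene_Score direction.
#' @export
select_prognostic <- function(genes, cohorts, p_threshold = 0.01) {
  res <- meta_analyse_genes(genes, cohorts)
  dropped <- res$gene_id[res$k_cohorts == 0L]
  if (length(dropped))
    message(length(dropped),
            " gene(s) usable in no cohort were excluded from selection")
  sel <- res[!is.na(res$p_value) & res$p_value < p_threshold, , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "all_results") <- res
  sel
}
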