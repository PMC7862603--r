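#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and returns the fitted step function as a
#' tidy table. Subjects censored at an event time are counted at risk at
#' that time, per the standard convention.
#'
#' @param time,event Survival outcome (months, 0/1 indicator).
#' @return A data.frame of class `km_curve`: `time` (ordered distinct
#'   observation times), `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' k-group log-rank test
#'
#' Observed-minus-expected event counts with hypergeometric variance,
#' referred to a chi-squared distribution on k - 1 degrees of freedom
#' (via [survival::survdiff()]).
#'
#' @param time,event Survival outcome.
#' @param group Group labels with k >= 2 levels present.
#' @return A list: `chi2`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (sum(event) < 1L) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(group))
}

#' Cox proportional-hazards regression
#'
#' Univariate or multivariate Cox regression via [survival::coxph()],
#' returning per-term hazard ratios with Wald 95% confidence intervals and
#' p-values. Categorical covariates are dummy-coded against their first
#' level. A rank-deficient design is an error naming the collinear terms.
#'
#' @param time,event Survival outcome.
#' @param covariates data.frame of covariates (numeric or factor/character).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A data.frame of class `cox_fit`: `term`, `beta`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`; attributes `converged`, `ties`,
#'   `n_events`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (!ncol(covariates)) stop("no covariates supplied")
  if (sum(event) < 1L) stop("no events observed")
  for (j in seq_along(covariates))
    if (is.character(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(sprintf("`%s`", colnames(covariates)),
                                        collapse = " + ")))
  fit <- survival::coxph(form, data = dat, ties = ties)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; collinear term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  out <- data.frame(term = names(beta), beta = unname(beta),
                    se = unname(se), hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * unname(se)),
                    ci_high = exp(unname(beta) + z * unname(se)),
                    p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- all(is.finite(beta)) && all(is.finite(se)) &&
    max(abs(beta)) < 15
  attr(out, "ties") <- ties
  attr(out, "n_events") <- sum(event)
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Survival validation of score strata
#'
#' The validation battery applied to a scored cohort: Kaplan-Meier curves
#' per stratum, a k-group log-rank test, a univariate Cox model on the
#' stratum factor (lowest stratum as reference), and, when covariates are
#' supplied, a multivariate Cox model adding them. When any populated
#' stratum holds fewer than `min_count` patients the four-way split
#' collapses to a two-way split at the central cut (score 25), recorded in
#' the report.
#'
#' @param scores An `mps_scores` data.frame ([compute_mps()] output).
#' @param clinical A [clinical_table()] for the same samples (joined on
#'   intersection).
#' @param covariates Optional character vector of clinical covariate
#'   columns for the multivariate model.
#' @param min_count Two-way-split trigger (default 10).
#' @param truncate_months Optional administrative censoring horizon, e.g.
#'   120 for a 10-year analysis.
#' @return A list of class `strata_report`: `km` (per-stratum curves),
#'   `logrank`, `cox_univariate`, `cox_multivariate` (or NULL), `strata_n`,
#'   `two_way` (logical), `n` (patients analysed).
#' @export
evaluate_strata <- function(scores, clinical, covariates = NULL,
                            min_count = 10, truncate_months = NULL) {
  stopifnot(inherits(clinical, "clinical_table"))
  shared <- intersect(scores$sample_id, clinical$sample_id)
  if (length(shared) < length(scores$sample_id) ||
      length(shared) < nrow(clinical))
    message("strata evaluation restricted to ", length(shared),
            " shared sample(s)")
  sc <- scores[match(shared, scores$sample_id), , drop = FALSE]
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  time <- cl$time; event <- cl$event
  if (!is.null(truncate_months)) {
    event <- ifelse(time > truncate_months, 0L, event)
    time <- pmin(time, truncate_months)
  }
  stratum <- sc$stratum
  counts <- table(factor(stratum, levels = 1:4))
  two_way <- any(counts > 0 & counts < min_count) || sum(counts > 0) < 2
  if (two_way) {
    stratum <- ifelse(sc$mps < 25, 1L, 2L)
    message("small stratum detected; falling back to a two-way split at 25")
  }
  f_strat <- factor(stratum)
  if (nlevels(f_strat) < 2L)
    stop("all patients fall in one stratum; nothing to compare")
  km <- lapply(split(seq_along(time), f_strat), function(idx)
    km_estimate(time[idx], event[idx]))
  lr <- logrank_test(time, event, f_strat)
  uni <- cox_fit(time, event, data.frame(stratum = f_strat))
  multi <- NULL
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, colnames(cl))
    if (length(miss))
      stop("covariate(s) not in clinical table: ",
           paste(miss, collapse = ", "))
    multi <- cox_fit(time, event,
                     cbind(data.frame(stratum = f_strat),
                           cl[, covariates, drop = FALSE]))
  }
  structure(list(km = km, logrank = lr, cox_univariate = uni,
                 cox_multivariate = multi,
                 strata_n = table(f_strat), two_way = two_way,
                 n = length(shared)),
            class = "strata_report")
}

#' @export
print.strata_report <- function(x, ...) {
  cat(sprintf("<strata_report> %d patients, %s split\n", x$n,
              if (x$two_way) "two-way" else "four-way"))
  print(x$strata_n)
  cat(sprintf("log-rank chi2 = %.3f (df %d), p = %.3g\n",
              x$logrank$chi2, x$logrank$df, x$logrank$p_value))
  invisible(x)
}
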