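#' Median-of-ratios size factors
#'
#' Library-size normalization for count matrices: each sample's size factor
#' is the median, over genes with a positive geometric mean, of that
#' sample's counts divided by the per-gene geometric mean across samples.
#'
#' @param counts Count matrix, genes x samples.
#' @return Positive numeric vector of size factors, one per sample.
#' @export
compute_size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no gene has all-positive counts; cannot compute size factors")
  sf <- apply(counts[use, , drop = FALSE], 2L,
              function(cnt) exp(stats::median(log(cnt) - log_gm[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor")
  sf
}

#' Estimate per-gene negative-binomial dispersion
#'
#' Method-of-moments estimate from within-group means and variances of
#' normalized counts, pooled across the two groups, then shrunk toward a
#' trended mean-dispersion fit (dispersion regressed on 1/mean, the usual
#' NB mean-variance trend). Estimates are floored at 1e-8; genes with zero
#' counts throughout are flagged and skipped.
#'
#' @param counts Count matrix, genes x samples.
#' @param group Two-level factor/vector of group labels, length =
#'   `ncol(counts)`.
#' @param size_factors Optional size factors; computed internally when
#'   omitted.
#' @param shrink Weight given to the trend in the shrunken estimate
#'   (0 = raw method of moments, 1 = pure trend).
#' @return A data.frame with columns `gene_id`, `dispersion`, `raw`,
#'   `trend`, `all_zero`.
#' @export
estimate_dispersion <- function(counts, group, size_factors = NULL,
                                shrink = 0.3) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (min(table(group)) < 2L) stop("need >= 2 samples per group")
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  norm <- sweep(counts, 2L, size_factors, "/")
  g1 <- group == levels(group)[1]
  mom_one <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1L, stats::var)
    list(mu = mu, phi = (v - mu) / mu^2)
  }
  a <- mom_one(norm[, g1, drop = FALSE])
  b <- mom_one(norm[, !g1, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(!g1)
  # pooled MoM, weighted by within-group degrees of freedom
  raw <- ((n1 - 1) * a$phi + (n2 - 1) * b$phi) / (n1 + n2 - 2)
  mu <- (n1 * a$mu + n2 * b$mu) / (n1 + n2)
  all_zero <- mu == 0
  raw[all_zero] <- NA_real_
  raw_floor <- pmax(raw, 1e-8)
  # trend: phi(mu) = a0 + a1/mu fitted to genes with informative estimates
  ok <- !all_zero & is.finite(raw) & mu > 0
  trend <- rep(1e-8, length(mu))
  if (sum(ok) >= 10) {
    fit <- stats::lm(y ~ x, data = data.frame(y = raw_floor[ok], x = 1 / mu[ok]))
    trend[!all_zero] <- pmax(fit$coefficients[1] +
                               fit$coefficients[2] / mu[!all_zero], 1e-8)
  } else if (any(ok)) {
    trend[!all_zero] <- pmax(mean(raw_floor[ok]), 1e-8)
  }
  phi <- pmax((1 - shrink) * raw_floor + shrink * trend, 1e-8)
  phi[all_zero] <- NA_real_
  data.frame(gene_id = rownames(counts), dispersion = phi, raw = raw,
             trend = trend, all_zero = all_zero,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized NB mean MLE with offsets (size factors) and fixed per-gene
# dispersion: Newton iterations on eta = log(mu), solving
# sum_i (y_i - s_i mu) / (1 + phi s_i mu) = 0 per gene.
nb_fit_mu <- function(counts, size_factors, phi, max_iter = 50L) {
  tot <- as.vector(counts %*% rep(1, ncol(counts)))
  mu <- pmax(tot / sum(size_factors), 1e-10)
  eta <- log(mu)
  s <- size_factors
  for (it in seq_len(max_iter)) {
    smu <- exp(eta) %o% s                      # genes x samples: s_i * mu_g
    denom <- 1 + phi * smu
    f <- rowSums((counts - smu) / denom)
    fp <- -rowSums(smu * (1 + phi * counts) / denom^2)
    step <- f / fp
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 2), -2)
    eta <- eta - step
    if (max(abs(step)) < 1e-10) break
  }
  exp(eta)
}

nb_loglik <- function(counts, size_factors, mu, phi) {
  mu_mat <- mu %o% size_factors
  size <- 1 / pmax(phi, 1e-12)
  ll <- stats::dnbinom(counts, size = size, mu = pmax(mu_mat, 1e-12),
                       log = TRUE)
  rowSums(ll)
}

#' Negative-binomial likelihood-ratio test for one gene
#'
#' Fits an NB generalized log-linear model with fixed dispersion under the
#' null (one mean) and the alternative (one mean per group), both with
#' size-factor offsets, and compares them by a likelihood-ratio test on one
#' degree of freedom. The fold-change is the ratio of fitted group means on
#' the normalized scale (second level vs first level of `group`).
#'
#' @param gene_counts Count vector across samples.
#' @param group Two-level group labels (first level = reference, e.g.
#'   normal; second level = e.g. tumor).
#' @param size_factors Positive size factors.
#' @param dispersion NB dispersion for the gene.
#' @return A list: `log2fc`, `lr_stat`, `p_value`, `flag` (non-empty for
#'   degenerate fits such as an all-zero group).
#' @export
nb_lrt <- function(gene_counts, group, size_factors, dispersion) {
  r <- nb_lrt_matrix(matrix(gene_counts, nrow = 1), group, size_factors,
                     dispersion)
  list(log2fc = r$log2fc[1], lr_stat = r$lr_stat[1], p_value = r$p_value[1],
       flag = r$flag[1])
}

# Matrix version used by call_degs: all genes at once.
nb_lrt_matrix <- function(counts, group, size_factors, dispersion) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  ref <- group == levels(group)[1]
  phi <- pmax(dispersion, 1e-8)
  phi[is.na(phi)] <- 1e-8
  mu0 <- nb_fit_mu(counts, size_factors, phi)
  mu1 <- nb_fit_mu(counts[, ref, drop = FALSE], size_factors[ref], phi)
  mu2 <- nb_fit_mu(counts[, !ref, drop = FALSE], size_factors[!ref], phi)
  ll0 <- nb_loglik(counts, size_factors, mu0, phi)
  ll1 <- nb_loglik(counts[, ref, drop = FALSE], size_factors[ref], mu1, phi)
  ll2 <- nb_loglik(counts[, !ref, drop = FALSE], size_factors[!ref], mu2, phi)
  lr <- pmax(2 * (ll1 + ll2 - ll0), 0)
  zero1 <- rowSums(counts[, ref, drop = FALSE]) == 0
  zero2 <- rowSums(counts[, !ref, drop = FALSE]) == 0
  flag <- ifelse(zero1 & zero2, "all_zero",
                 ifelse(zero1 | zero2, "one_group_zero", ""))
  log2fc <- log2(pmax(mu2, 1e-10) / pmax(mu1, 1e-10))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  p[flag == "all_zero"] <- NA_real_
  data.frame(log2fc = log2fc, lr_stat = lr, p_value = p, flag = flag,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in [0, 1]; `NA` is rejected.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values)) stop("NA p-values are not allowed")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between tumor and normal counts
#'
#' The first selection filter: per-gene NB likelihood-ratio tests between
#' the two arms, Benjamini-Hochberg FDR adjustment, and joint strict
#' thresholds — a gene is a DEG iff q < `fdr_threshold` AND |log2 fold
#' change| > `lfc_threshold` (defaults 0.01 and 1, i.e. expression differs
#' by a factor of more than 2 in either direction).
#'
#' @param tumor,normal Count-scale [expression_matrix()] objects sharing a
#'   gene set (the intersection is used; none shared is an error).
#' @param fdr_threshold,lfc_threshold Strict cutoffs as described.
#' @return A data.frame (one row per shared gene): `gene_id`, `log2fc`
#'   (tumor vs normal), `lr_stat`, `p_value`, `q_value`, `is_deg`, `flag`.
#'   Genes with undefined tests (all-zero in both arms) have `NA` p/q and
#'   `is_deg = FALSE`.
#' @export
call_degs <- function(tumor, normal, fdr_threshold = 0.01,
                      lfc_threshold = 1) {
  stopifnot(inherits(tumor, "expr_matrix"), inherits(normal, "expr_matrix"))
  if (attr(tumor, "scale") != "count" || attr(normal, "scale") != "count")
    stop("DEG calling requires count-scale matrices")
  shared <- intersect(rownames(tumor), rownames(normal))
  if (!length(shared)) stop("tumor and normal matrices share no genes")
  counts <- cbind(unclass(normal)[shared, , drop = FALSE],
                  unclass(tumor)[shared, , drop = FALSE])
  group <- factor(rep(c("normal", "tumor"),
                      c(ncol(normal), ncol(tumor))),
                  levels = c("normal", "tumor"))
  if (anyNA(counts)) stop("missing values in count matrices")
  sf <- compute_size_factors(counts)
  disp <- estimate_dispersion(counts, group, size_factors = sf)
  res <- nb_lrt_matrix(counts, group, sf, disp$dispersion)
  ok <- !is.na(res$p_value)
  q <- rep(NA_real_, nrow(res))
  q[ok] <- bh_fdr(res$p_value[ok])
  is_deg <- !is.na(q) & q < fdr_threshold & abs(res$log2fc) > lfc_threshold
  data.frame(gene_id = shared, log2fc = res$log2fc, lr_stat = res$lr_stat,
             p_value = res$p_value, q_value = q, is_deg = is_deg,
             flag = res$flag, stringsAsFactors = FALSE, row.names = NULL)
}
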