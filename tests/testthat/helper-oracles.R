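# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive implementation (brute force, grid search, explicit
# hand formulas) kept separate from the package's own code paths.

# Benjamini-Hochberg step-up by brute force: q_(k) = min_{i >= k} m p_(i) / i
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Breslow-ties Cox log partial likelihood for one binary covariate,
# computed by explicit loops over event times.
oracle_breslow_loglik <- function(beta, status, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * status[i] - log(sum(exp(beta * status[risk])))
  }
  ll
}

# Grid-maximized Breslow partial likelihood over beta in [-5, 5].
oracle_cox_grid <- function(status, time, event, step = 1e-4) {
  grid <- seq(-5, 5, by = step)
  ll <- vapply(grid, oracle_breslow_loglik, numeric(1),
               status = status, time = time, event = event)
  grid[which.max(ll)]
}

# DerSimonian-Laird pooling written out by hand.
oracle_dl <- function(theta, se) {
  k <- length(theta)
  w <- 1 / se^2
  fe <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - fe)^2)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  wr <- 1 / (se^2 + tau2)
  est <- sum(wr * theta) / sum(wr)
  se_p <- sqrt(1 / sum(wr))
  list(est = est, se = se_p, tau2 = tau2, q = q,
       p = 2 * stats::pnorm(-abs(est / se_p)))
}

# Product-limit estimator by an explicit loop over distinct event times.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (i in seq_along(et)) {
    r <- sum(time >= et[i])
    d <- sum(time == et[i] & event == 1)
    s <- s * (1 - d / r)
    surv[i] <- s
  }
  data.frame(time = et, survival = surv)
}

# Two-group log-rank chi-squared from the 2x2 table at each event time.
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(as.factor(group)) - 1L
  et <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in et) {
    at_risk <- time >= t
    r <- sum(at_risk); r1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o <- o + d1
    e <- e + d * r1 / r
    if (r > 1) v <- v + d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1)
  }
  (o - e)^2 / v
}

# Small reproducible survival cohort used across tests.
make_toy_cohort <- function(n = 60, n_genes = 8, seed = 99,
                            endpoint = "RFS") {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * n, 6, 1), n_genes, n,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n))))
  time <- rexp(n, 0.03)
  event <- rbinom(n, 1, 0.6)
  cohort_dataset("toy",
                 expression_matrix(expr, "log"),
                 clinical_table(colnames(expr), time, event,
                                endpoint = endpoint),
                 quiet = TRUE)
}
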