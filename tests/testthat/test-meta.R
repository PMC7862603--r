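test_that("median dichotomization follows the tie-goes-low convention", {
  s1 <- dichotomize_at_median(c(1, 2, 3, 4, 5))
  expect_equal(as.integer(s1), c(0L, 0L, 0L, 1L, 1L))
  expect_false(attr(s1, "degenerate"))
  s2 <- dichotomize_at_median(c(1, 2, 3, 4))
  expect_equal(as.integer(s2), c(0L, 0L, 1L, 1L))
  s3 <- dichotomize_at_median(c(7, 7, 7))
  expect_true(attr(s3, "degenerate"))
  expect_error(dichotomize_at_median(c(1, NA, 3)), "missing")
})

test_that("the univariate Cox fit matches grid search and the survival package", {
  # symmetry: identical outcome data in both groups
  tt <- c(3, 5, 8, 12, 3, 5, 8, 12)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  st <- rep(c(0, 1), each = 4)
  expect_lt(abs(cohort_hr(st, tt, ev)$log_hr), 1e-8)

  # 8-subject toys against the grid-maximized Breslow likelihood
  set.seed(41)
  for (r in 1:5) {
    time <- sample(1:20, 8, replace = TRUE)
    event <- rbinom(8, 1, 0.8)
    status <- rep(c(0, 1), 4)
    if (sum(event) == 0 || length(unique(status[event == 1])) < 1) next
    fit <- cohort_hr(status, time, event)
    if (!fit$converged) next
    expect_lt(abs(fit$log_hr - oracle_cox_grid(status, time, event)), 1e-4)
  }

  # larger datasets with ties against survival::coxph (Breslow)
  for (r in 1:10) {
    n <- 80
    time <- sample(1:30, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    status <- rbinom(n, 1, 0.5)
    if (sum(event) < 2 || length(unique(status)) < 2) next
    ref <- survival::coxph(survival::Surv(time, event) ~ status,
                           ties = "breslow")
    fit <- cohort_hr(status, time, event)
    expect_equal(fit$log_hr, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
  }

  expect_error(cohort_hr(c(0, 1, 0, 1), c(1, 2, 3, 4), c(0, 0, 0, 0)),
               "events")
  expect_error(cohort_hr(c(1, 1, 1), c(1, 2, 3), c(1, 1, 0)), "both status")
})

test_that("random-effects pooling reproduces the DerSimonian-Laird formulas", {
  one <- pool_random_effects(0.3, 0.1)
  expect_equal(one$pooled_log_hr, 0.3)
  expect_equal(one$pooled_se, 0.1)
  expect_equal(one$tau2, 0)

  hom <- pool_random_effects(rep(0.5, 3), rep(0.2, 3))
  expect_equal(hom$pooled_log_hr, 0.5)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$q_stat, 0)

  th <- c(0.2, 0.6, -0.1); se <- c(0.10, 0.20, 0.15)
  got <- pool_random_effects(th, se)
  want <- oracle_dl(th, se)
  expect_lt(abs(got$pooled_log_hr - want$est), 1e-10)
  expect_lt(abs(got$pooled_se - want$se), 1e-10)
  expect_lt(abs(got$tau2 - want$tau2), 1e-10)
  expect_lt(abs(got$p_value - want$p), 1e-10)

  # independent ecosystem cross-check
  mf <- metafor::rma(yi = th, sei = se, method = "DL")
  expect_equal(got$pooled_log_hr, as.numeric(mf$beta), tolerance = 1e-8)
  expect_equal(got$tau2, mf$tau2, tolerance = 1e-8)

  # tau2 never negative; pooled stays inside the convex hull
  set.seed(42)
  for (r in 1:50) {
    k <- sample(2:6, 1)
    thr <- rnorm(k, 0, 0.5); ser <- runif(k, 0.05, 0.4)
    m <- pool_random_effects(thr, ser)
    expect_gte(m$tau2, 0)
    expect_gte(m$pooled_log_hr, min(thr) - 1e-12)
    expect_lte(m$pooled_log_hr, max(thr) + 1e-12)
  }
  expect_error(pool_random_effects(numeric(0), numeric(0)), "no cohort")
})

test_that("the meta filter finds planted genes and skips unusable ones", {
  hits <- vapply(1:10, function(r) {
    cfg <- sim_config(n_genes = 20, n_planted_deg = 0, n_planted_prognostic = 1,
                      beta_planted = 0.7, direction_planted = "up",
                      n_cohorts = 4, n_per_cohort = 150, censor_rate = 0.3)
    sv <- simulate_survival_cohorts(cfg, seed = 900 + r)
    sel <- select_prognostic(sprintf("gene%04d", 1:20), sv$cohorts, 0.01)
    "gene0001" %in% sel$gene_id
  }, logical(1))
  expect_gte(sum(hits), 9L)

  co <- make_toy_cohort()
  expect_message(sel <- select_prognostic(c("g01", "absent_gene"), list(co)),
                 "no cohort")
  res <- attr(sel, "all_results")
  expect_equal(res$k_cohorts[res$gene_id == "absent_gene"], 0L)
})

test_that("dichotomization makes hazard ratios platform-invariant", {
  co <- make_toy_cohort(n = 80, seed = 11)
  vals <- unclass(co$expression)["g01", ]
  h1 <- cohort_hr(dichotomize_at_median(vals),
                  co$clinical$time, co$clinical$event)
  h2 <- cohort_hr(dichotomize_at_median(vals + 3.7),
                  co$clinical$time, co$clinical$event)
  expect_identical(h1$log_hr, h2$log_hr)
  expect_identical(h1$se, h2$se)
})

test_that("vectorized meta-analysis equals the scalar path gene by gene", {
  cfg <- sim_config(n_genes = 12, n_planted_deg = 0, n_planted_prognostic = 3,
                    n_cohorts = 3, n_per_cohort = 100, censor_rate = 0.3)
  sv <- simulate_survival_cohorts(cfg, seed = 61)
  res <- meta_analyse_genes(sprintf("gene%04d", 1:12), sv$cohorts)
  for (g in c("gene0001", "gene0007")) {
    lh <- c(); se <- c()
    for (co in sv$cohorts) {
      st <- dichotomize_at_median(unclass(co$expression)[g, ])
      h <- cohort_hr(st, co$clinical$time, co$clinical$event)
      lh <- c(lh, h$log_hr); se <- c(se, h$se)
    }
    m <- pool_random_effects(lh, se)
    row <- res[res$gene_id == g, ]
    expect_equal(row$pooled_log_hr, m$pooled_log_hr, tolerance = 1e-12)
    expect_equal(row$p_value, m$p_value, tolerance = 1e-12)
    expect_equal(row$tau2, m$tau2, tolerance = 1e-12)
  }
})
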