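test_that("Kaplan-Meier estimates reduce to hand computations", {
  # no censoring: survival = 1 - empirical CDF at event times
  tt <- c(2, 5, 5, 9, 11)
  km <- km_estimate(tt, rep(1, 5))
  ev <- km$n_event > 0
  expect_equal(km$survival[ev],
               1 - ecdf(tt)(km$time[ev]))

  # all censored: flat at 1
  km2 <- km_estimate(c(3, 6, 8), c(0, 0, 0))
  expect_true(all(km2$survival == 1))

  # 6-subject toy with a tie and interleaved censoring
  time <- c(1, 2, 2, 3, 4, 5); event <- c(1, 1, 0, 1, 0, 1)
  km3 <- km_estimate(time, event)
  hand <- oracle_km(time, event)
  got <- km3[km3$n_event > 0, c("time", "survival")]
  expect_equal(got$time, hand$time)
  expect_equal(got$survival, hand$survival, tolerance = 1e-12)
  expect_true(all(diff(km3$survival) <= 0))
})

test_that("log-rank statistics match the event-time table computation", {
  # identical groups: exactly zero
  tt <- c(3, 7, 9, 12); ev <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_lt(lr0$chi2, 1e-12)
  expect_equal(lr0$p_value, 1)

  # k = 4 groups gives 3 degrees of freedom
  set.seed(71)
  lr4 <- logrank_test(rexp(80, 0.1), rbinom(80, 1, 0.7),
                      rep(1:4, each = 20))
  expect_equal(lr4$df, 3L)

  # 10-subject two-group toy against the hand oracle
  time <- c(1, 3, 3, 5, 7, 2, 2, 6, 8, 9)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0, 1, 0)
  group <- rep(c("A", "B"), each = 5)
  lr <- logrank_test(time, event, group)
  expect_lt(abs(lr$chi2 - oracle_logrank2(time, event, group)), 1e-10)

  # invariances: group relabeling and time translation
  lr_b <- logrank_test(time + 100, event, rev(group))
  expect_equal(lr_b$chi2, lr$chi2, tolerance = 1e-12)

  expect_error(logrank_test(time, event, rep("A", 10)), "two groups")
})

test_that("the chi-squared log-rank p agrees with a permutation null", {
  set.seed(72)
  n <- 60
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.7)
  group <- rep(c(0, 1), each = n / 2)
  obs <- oracle_logrank2(time, event, group)
  perm <- replicate(1e4, oracle_logrank2(time, event, sample(group)))
  p_perm <- mean(perm >= obs - 1e-12)
  p_chi2 <- logrank_test(time, event, group)$p_value
  expect_lt(abs(p_perm - p_chi2), 0.01)
})

test_that("Cox regression is consistent internally and recovers parameters", {
  co <- make_toy_cohort(n = 90, seed = 12)
  st <- as.integer(dichotomize_at_median(unclass(co$expression)["g01", ]))
  uni <- cox_fit(co$clinical$time, co$clinical$event,
                 data.frame(status = st))
  hr <- cohort_hr(st, co$clinical$time, co$clinical$event)
  expect_lt(abs(uni$beta - hr$log_hr), 1e-8)
  expect_lt(abs(uni$se - hr$se), 1e-8)
  expect_true(uni$ci_low < uni$hr & uni$hr < uni$ci_high)

  # two-covariate recovery from exponential survival
  ests <- t(vapply(1:10, function(r) {
    set.seed(100 + r)
    n <- 2000
    x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
    h <- 0.02 * exp(0.7 * x1 - 0.3 * x2)
    tev <- rexp(n, h); tc <- rexp(n, 0.02)
    cox_fit(pmin(tev, tc), as.integer(tev <= tc),
            data.frame(x1 = x1, x2 = x2))$beta
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1]) - 0.7), 0.1)
  expect_lt(abs(mean(ests[, 2]) + 0.3), 0.1)

  # duplicated covariate: rank deficiency is reported by term
  expect_error(cox_fit(co$clinical$time, co$clinical$event,
                       data.frame(a = st, b = st)), "collinear")
})

test_that("strata evaluation stratifies planted risk and falls back cleanly", {
  sig <- mps_colon_signature()
  set.seed(73)
  ok <- vapply(1:5, function(r) {
    n <- 600
    scores <- runif(n, 0, 50)
    h <- 0.01 * exp(0.05 * (scores - 25))
    tev <- rexp(n, h); tc <- rexp(n, 0.01)
    sc <- data.frame(sample_id = paste0("p", 1:n), mps = scores,
                     stratum = stratify(scores))
    class(sc) <- c("mps_scores", "data.frame")
    cl <- clinical_table(sc$sample_id, pmin(tev, tc),
                         as.integer(tev <= tc))
    rep <- evaluate_strata(sc, cl)
    mono <- if (rep$two_way) rep$cox_univariate$beta > 0 else
      all(diff(c(0, rep$cox_univariate$beta)) > 0)
    rep$logrank$p_value < 0.01 && mono
  }, logical(1))
  expect_gte(sum(ok), 4L)

  # a sparse stratum triggers the two-way split at the central cut
  n <- 80
  scores2 <- c(runif(n - 3, 0, 24), 47, 48, 49)
  sc2 <- data.frame(sample_id = paste0("q", 1:n), mps = scores2,
                    stratum = stratify(scores2))
  class(sc2) <- c("mps_scores", "data.frame")
  cl2 <- clinical_table(sc2$sample_id, rexp(n, 0.05), rbinom(n, 1, 0.8))
  expect_message(rep2 <- evaluate_strata(sc2, cl2), "two-way")
  expect_true(rep2$two_way)

  # independent scores: log-rank p-values look uniform
  set.seed(74)
  ps <- vapply(1:100, function(r) {
    n <- 200
    scores <- runif(n, 0, 50)
    cl <- clinical_table(paste0("r", 1:n), rexp(n, 0.03),
                         rbinom(n, 1, 0.7))
    sc <- data.frame(sample_id = cl$sample_id, mps = scores,
                     stratum = stratify(scores))
    class(sc) <- c("mps_scores", "data.frame")
    suppressMessages(evaluate_strata(sc, cl)$logrank$p_value)
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # administrative truncation censors beyond the horizon
  set.seed(75)
  cl3 <- clinical_table(sc2$sample_id, rexp(n, 0.005), rbinom(n, 1, 0.8))
  rep3 <- suppressMessages(evaluate_strata(sc2, cl3,
                                           truncate_months = 120))
  expect_true(all(unlist(lapply(rep3$km, function(k) k$time)) <= 120))
})
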