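test_that("the truncated-survival target maps months onto [0, 60]", {
  expect_equal(build_target(24), 36)
  expect_equal(build_target(80), 0)
  expect_equal(build_target(60), 0)
  expect_equal(build_target(c(1, 59.5)), c(59, 0.5))
  expect_error(build_target(0), "positive")
})

test_that("coordinate descent matches closed-form solutions", {
  set.seed(51)
  n <- 60; p <- 5
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("g", 1:p)))
  beta_true <- c(3, -2, 0, 1, 0)
  y <- 10 + X %*% beta_true + rnorm(n, 0, 0.5)

  # lambda = 0: ordinary least squares via the normal equations
  fit0 <- lasso_fit(X, y, lambda = 0)
  ls <- coef(lm(y ~ X))
  expect_lt(max(abs(fit0$beta - ls[-1])), 1e-6)
  expect_lt(abs(fit0$intercept - ls[1]), 1e-6)

  # beyond the deactivation bound every coefficient is zero
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  fit_max <- lasso_fit(X, y, lambda = lam_max * 1.0001)
  expect_true(all(fit_max$beta == 0))

  # orthonormalized design: soft-thresholded univariate solutions
  set.seed(52)
  Z <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), center = TRUE,
                     scale = FALSE))) * sqrt(n)
  colnames(Z) <- paste0("z", 1:p)
  yz <- rnorm(n, sd = 2)
  lam <- 0.3
  fitz <- lasso_fit(Z, yz, lambda = lam, tol = 1e-10)
  soft <- function(a, g) sign(a) * pmax(abs(a) - g, 0)
  closed <- soft(as.vector(crossprod(Z, yz - mean(yz))) / n, lam)
  expect_lt(max(abs(fitz$beta - closed)), 1e-8)
})

test_that("coordinate descent agrees with glmnet on the shared objective", {
  set.seed(53)
  n <- 100; p <- 12
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("g", 1:p)))
  y <- 5 + X[, 1] * 4 - X[, 2] * 3 + rnorm(n)
  for (lam in c(0.05, 0.5)) {
    mine <- lasso_fit(X, y, lambda = lam, tol = 1e-10)
    gn <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                         thresh = 1e-14)
    expect_lt(max(abs(mine$beta - as.vector(gn$beta))), 1e-5)
  }
})

test_that("constant-zero predictors are dropped with a warning", {
  X <- cbind(a = c(1, 0, 1, 0), b = c(0, 0, 0, 0))
  expect_warning(fit <- lasso_fit(X, c(2, 0, 2, 0), lambda = 0.01), "b")
  expect_equal(unname(fit$beta["b"]), 0)
  expect_error(lasso_fit(cbind(a = c(1, NA)), c(1, 2), 0.1), "non-finite")
})

test_that("signature extraction renormalizes weights and maps directions", {
  meta <- data.frame(gene_id = c("a", "b", "c"),
                     integrated_hr = c(1.5, 0.7, 2.0))
  one <- extract_signature(c(a = 0.8, b = 0, c = 0), meta)
  expect_equal(one$weight, 50)
  expect_equal(one$direction, "HIGH")

  sig <- extract_signature(c(a = 2, b = -2, c = 1), meta)
  expect_equal(sig$weight, c(20, 20, 10))
  expect_equal(sig$direction, c("HIGH", "LOW", "HIGH"))
  expect_identical(attr(sig, "score_max"), 50)
  expect_error(extract_signature(c(a = 0, b = 0), meta), "penalty too large")
})

test_that("train/validation splits are seeded and event-stratified", {
  co <- make_toy_cohort(n = 100, seed = 3)
  sp <- split_train_validation(co, 0.5, seed = 9)
  expect_equal(ncol(sp$training$expression), 50)
  ev_tr <- mean(sp$training$clinical$event)
  ev_va <- mean(sp$validation$clinical$event)
  expect_lte(abs(sum(sp$training$clinical$event) -
                 sum(sp$validation$clinical$event)), 1)
  sp2 <- split_train_validation(co, 0.5, seed = 9)
  expect_identical(sp$training$clinical$sample_id,
                   sp2$training$clinical$sample_id)
  expect_warning(sp3 <- split_train_validation(co, 1, seed = 1), "empty")
  expect_null(sp3$validation)
})

test_that("lambda tuning minimizes validation error over the grid", {
  set.seed(54)
  n <- 200; p <- 50
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("g", 1:p)))
  y <- 20 + X[, 1] * 8 + X[, 2] * 6 - X[, 3] * 7 + rnorm(n, 0, 2)
  tr <- 1:120; va <- 121:200
  tuned <- tune_lambda(X[tr, ], y[tr], X[va, ], y[va])
  expect_equal(min(tuned$mse), unname(tuned$mse[as.character(tuned$lambda)]))
  expect_lt(tuned$mse[as.character(tuned$lambda)],
            1.1 * min(tuned$mse))
  single <- tune_lambda(X[tr, ], y[tr], X[va, ], y[va], grid = 0.5)
  expect_equal(single$lambda, 0.5)
  expect_error(tune_lambda(X[tr, ], y[tr], X[va, ], y[va],
                           grid = numeric(0)), "empty")
  expect_error(tune_lambda(X[tr, ], y[tr], NULL, NULL), "validation")

  # sparsity is non-increasing along the penalty grid
  nz <- vapply(c(0.01, 0.05, 0.1, 0.5, 1, 5),
               function(l) sum(lasso_fit(X[tr, ], y[tr], l)$beta != 0),
               numeric(1))
  expect_true(all(diff(nz) <= 0))
})
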