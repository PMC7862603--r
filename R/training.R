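#' Truncated-survival regression target
#'
#' The training target is the portion of a five-year window a patient did
#' NOT survive event-free: y = cap - min(t, cap) with cap = 60 months, so
#' early relapse maps to large y and five event-free years map to 0.
#' Follow-up times are used as recorded (time to event or to censoring);
#' restrict the cohort first if an events-only analysis is wanted.
#'
#' @param dfs_months Positive follow-up times in months.
#' @param cap Truncation horizon (default 60).
#' @return Numeric vector in [0, cap].
#' @export
build_target <- function(dfs_months, cap = 60) {
  if (any(!is.finite(dfs_months) | dfs_months <= 0))
    stop("follow-up times must be positive")
  cap - pmin(dfs_months, cap)
}

#' L1-penalized linear regression by coordinate descent
#'
#' Minimizes (1/2n) * ||y - b0 - X b||^2 + lambda * sum(|b|) with an
#' unpenalized intercept and NO predictor re-standardization (the design is
#' expected to hold binary Gene_Score columns, already on a common scale).
#' Cyclic coordinate descent with soft-thresholding; deterministic given
#' the column order.
#'
#' @param X Numeric design matrix (patients x genes), with column names.
#' @param y Response vector.
#' @param lambda Non-negative L1 penalty.
#' @param tol Convergence tolerance on the largest coefficient change.
#' @param max_iter Maximum number of full sweeps.
#' @return A list: `beta` (named coefficients), `intercept`, `lambda`,
#'   `iterations`, `converged`, `dropped` (names of constant-zero columns
#'   removed, which get coefficient 0).
#' @export
lasso_fit <- function(X, y, lambda = 0.5, tol = 1e-7, max_iter = 1e5) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in design or response")
  if (lambda < 0) stop("lambda must be non-negative")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  col_ss <- colSums(X^2) / n
  dropped <- colnames(X)[col_ss == 0]
  keep <- col_ss > 0
  Xk <- X[, keep, drop = FALSE]
  ss <- col_ss[keep]
  p <- ncol(Xk)
  beta <- rep(0, p)
  b0 <- mean(y)
  r <- y - b0
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    delta_max <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      z <- sum(Xk[, j] * r) / n + ss[j] * bj_old
      bj <- soft(z, lambda) / ss[j]
      if (bj != bj_old) {
        r <- r - (bj - bj_old) * Xk[, j]
        beta[j] <- bj
        delta_max <- max(delta_max, abs(bj - bj_old))
      }
    }
    b0_new <- b0 + mean(r)
    r <- r - (b0_new - b0)
    delta_max <- max(delta_max, abs(b0_new - b0))
    b0 <- b0_new
    if (delta_max < tol) { converged <- TRUE; break }
  }
  if (length(dropped))
    warning("dropped constant-zero column(s): ",
            paste(dropped, collapse = ", "))
  full <- stats::setNames(rep(0, ncol(X)), colnames(X))
  full[colnames(Xk)] <- beta
  list(beta = full, intercept = b0, lambda = lambda, iterations = it,
       converged = converged, dropped = dropped)
}

#' Extract a normalized signature from lasso coefficients
#'
#' Keeps genes with nonzero coefficients, rescales their absolute
#' coefficients so the weights sum exactly to `score_max` (making the
#' all-unfavourable patient score `score_max`), and takes each gene's
#' scoring direction from its integrated hazard ratio: HIGH if HR > 1, LOW
#' if HR < 1.
#'
#' @param coefs Named coefficient vector from [lasso_fit()] (`$beta`).
#' @param meta Meta-analysis table (from [select_prognostic()] /
#'   [meta_analyse_genes()]) supplying `integrated_hr` per gene.
#' @param score_max Target score maximum (default 50).
#' @param zero_tol Coefficients with |b| at or below this are treated as
#'   zero.
#' @return An [mps_signature()].
#' @export
extract_signature <- function(coefs, meta, score_max = 50,
                              zero_tol = 1e-12) {
  nz <- which(abs(coefs) > zero_tol)
  if (!length(nz))
    stop("penalty too large: all coefficients are zero")
  genes <- names(coefs)[nz]
  miss <- setdiff(genes, meta$gene_id)
  if (length(miss))
    stop("no integrated HR available for: ", paste(miss, collapse = ", "))
  hr <- meta$integrated_hr[match(genes, meta$gene_id)]
  w <- abs(coefs[nz])
  mps_signature(gene_id = genes,
                direction = ifelse(hr > 1, "HIGH", "LOW"),
                weight = score_max * w / sum(w),
                score_max = score_max)
}

#' Split a cohort into training and validation halves
#'
#' Seeded random split, stratified by event status so both halves keep the
#' same event proportion (within one patient per stratum).
#'
#' @param cohort A [cohort_dataset()].
#' @param fraction Training fraction (default 0.5).
#' @param seed Integer seed.
#' @return A list with `training` and `validation` [cohort_dataset()]s
#'   (validation may be empty, with a warning, when `fraction = 1`).
#' @export
split_train_validation <- function(cohort, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  n <- nrow(cohort$clinical)
  if (n < 4L) stop("need at least 4 patients to split")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  set.seed(seed)
  ids <- cohort$clinical$sample_id
  train_ids <- unlist(lapply(split(ids, cohort$clinical$event), function(g) {
    sample(g, round(length(g) * fraction))
  }), use.names = FALSE)
  val_ids <- setdiff(ids, train_ids)
  subset_cohort <- function(keep, tag) {
    expr <- cohort$expression[, keep, drop = FALSE]
    attr(expr, "scale") <- attr(cohort$expression, "scale")
    class(expr) <- class(cohort$expression)
    clin <- cohort$clinical[match(keep, cohort$clinical$sample_id), ,
                            drop = FALSE]
    rownames(clin) <- NULL
    attr(clin, "endpoint") <- attr(cohort$clinical, "endpoint")
    class(clin) <- class(cohort$clinical)
    cohort_dataset(paste0(cohort$name, tag), expr, clin, quiet = TRUE)
  }
  if (!length(val_ids)) {
    warning("validation set is empty (fraction = 1)")
    return(list(training = subset_cohort(train_ids, "_training"),
                validation = NULL))
  }
  list(training = subset_cohort(train_ids, "_training"),
       validation = subset_cohort(val_ids, "_validation"))
}

#' Choose the L1 penalty on a validation set
#'
#' Fits [lasso_fit()] at every grid value on the training data and returns
#' the value minimizing validation mean-squared error; ties go to the
#' smaller lambda.
#'
#' @param X,y Training design and target.
#' @param X_val,y_val Validation design and target (non-empty).
#' @param grid Candidate penalties (default the canonical five-point grid).
#' @return A list: `lambda` (chosen), `mse` (named vector over the grid).
#' @export
tune_lambda <- function(X, y, X_val, y_val,
                        grid = c(0.01, 0.05, 0.1, 0.5, 1)) {
  if (!length(grid)) stop("empty lambda grid")
  if (is.null(X_val) || !NROW(X_val)) stop("validation set is empty")
  grid <- sort(grid)
  mse <- vapply(grid, function(lam) {
    f <- lasso_fit(X, y, lambda = lam)
    pred <- f$intercept + as.vector(as.matrix(X_val) %*% f$beta)
    mean((y_val - pred)^2)
  }, numeric(1))
  names(mse) <- as.character(grid)
  list(lambda = grid[which.min(mse)], mse = mse)
}
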