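#' Binary Gene_Score from expression status and integrated hazard ratio
#'
#' The step function mapping a patient's median-relative expression status
#' for one gene and that gene's pooled (integrated) hazard ratio onto a
#' binary risk contribution: the score is 1 exactly when the patient sits
#' in the gene's unfavourable group — LOW expression of a protective gene
#' (HR < 1) or HIGH expression of a harmful gene (HR > 1).
#'
#' @param status `"LOW"` or `"HIGH"` (or 0/1).
#' @param integrated_hr Positive pooled hazard ratio.
#' @return 0 or 1. An HR of exactly 1 falls outside the step function's
#'   cases and returns 0 with a warning.
#' @export
gene_score <- function(status, integrated_hr) {
  if (!is.finite(integrated_hr) || integrated_hr <= 0)
    stop("integrated_hr must be a positive number")
  if (is.numeric(status)) status <- ifelse(status > 0, "HIGH", "LOW")
  status <- toupper(status)
  if (!status %in% c("LOW", "HIGH")) stop("status must be LOW or HIGH")
  if (integrated_hr == 1) {
    warning("integrated HR is exactly 1; gene carries no direction, score 0")
    return(0L)
  }
  as.integer((status == "LOW") == (integrated_hr < 1))
}

#' Binarize a cohort's expression against a signature
#'
#' Per signature gene: dichotomize expression at the median of the cohort
#' being scored (ties count as LOW), then apply the gene's scoring
#' direction — HIGH-direction genes score 1 above the median, LOW-direction
#' genes score 1 at or below it. Medians are always recomputed on the
#' scored cohort, which is what makes the score platform-independent; pass
#' `medians` to override with externally fixed cutoffs (single-sample use).
#'
#' @param expr An [expression_matrix()] containing every signature gene
#'   (missing genes are an error listing them).
#' @param signature An [mps_signature()].
#' @param medians Optional named vector of fixed per-gene cutoffs.
#' @param min_samples Below this cohort size a warning flags the median as
#'   unstable.
#' @return Binary matrix (signature genes x samples) of Gene_Score values.
#' @export
binarize_cohort <- function(expr, signature, medians = NULL,
                            min_samples = 10) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(signature, "mps_signature"))
  missing_genes <- setdiff(signature$gene_id, rownames(expr))
  if (length(missing_genes))
    stop("signature gene(s) missing from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  if (ncol(expr) < min_samples)
    warning("cohort has fewer than ", min_samples,
            " samples; within-cohort medians may be unstable")
  vals <- unclass(expr)[signature$gene_id, , drop = FALSE]
  if (anyNA(vals))
    stop("missing expression values for signature gene(s): ",
         paste(signature$gene_id[rowSums(is.na(vals)) > 0], collapse = ", "))
  if (is.null(medians)) {
    medians <- apply(vals, 1L, stats::median)
    degen <- apply(vals, 1L, function(x) length(unique(x)) < 2L)
    if (any(degen))
      warning("constant expression within cohort for: ",
              paste(signature$gene_id[degen], collapse = ", "))
  } else {
    if (!all(signature$gene_id %in% names(medians)))
      stop("fixed medians missing for some signature genes")
    medians <- medians[signature$gene_id]
  }
  high <- (vals > medians) * 1
  scores <- ifelse(signature$direction == "HIGH", 1, 0) * high +
    ifelse(signature$direction == "LOW", 1, 0) * (1 - high)
  dimnames(scores) <- dimnames(vals)
  scores
}

#' Weighted molecular prognostic score
#'
#' The mPS of each patient is the weight-by-score inner product over the
#' signature: score_j = sum_i weight_i * gene_score_ij, ranging from 0 (no
#' unfavourable statuses) to `score_max` (all unfavourable).
#'
#' @param scores Binary matrix from [binarize_cohort()] (signature genes x
#'   samples).
#' @param signature The [mps_signature()] supplying the weights.
#' @return A data.frame of class `mps_scores`: `sample_id`, `mps`,
#'   `stratum` (via [stratify()]).
#' @export
compute_mps <- function(scores, signature) {
  stopifnot(inherits(signature, "mps_signature"))
  miss <- setdiff(signature$gene_id, rownames(scores))
  if (length(miss))
    stop("score matrix missing signature gene(s): ",
         paste(miss, collapse = ", "))
  s <- scores[signature$gene_id, , drop = FALSE]
  if (!all(s %in% c(0, 1))) stop("gene scores must be binary")
  mps <- as.vector(crossprod(s, signature$weight))
  out <- data.frame(sample_id = colnames(scores), mps = mps,
                    stratum = stratify(mps, attr(signature, "score_max")),
                    stringsAsFactors = FALSE)
  class(out) <- c("mps_scores", "data.frame")
  out
}

#' Four-way risk stratification of mPS values
#'
#' Assigns the published risk strata: 1 for scores below 10, 2 for [10, 25),
#' 3 for [25, 40) and 4 for 40 up to the maximum. Cut points are
#' left-closed, so a score exactly at a boundary joins the higher stratum.
#'
#' @param score Numeric mPS values in [0, score_max].
#' @param score_max Upper bound of the score (default 50).
#' @param cuts The three interior cut points.
#' @return Integer strata (1-4), same length as `score`.
#' @export
stratify <- function(score, score_max = 50, cuts = c(10, 25, 40)) {
  if (any(!is.finite(score) | score < 0 | score > score_max))
    stop("scores must lie in [0, score_max]")
  as.integer(findInterval(score, cuts) + 1L)
}

#' Score a cohort with a signature
#'
#' Convenience wrapper: [binarize_cohort()] then [compute_mps()].
#'
#' @param cohort A [cohort_dataset()] (or an [expression_matrix()]).
#' @param signature An [mps_signature()].
#' @param ... Passed to [binarize_cohort()].
#' @return An `mps_scores` data.frame.
#' @export
score_cohort <- function(cohort, signature, ...) {
  expr <- if (inherits(cohort, "cohort_dataset")) cohort$expression else cohort
  compute_mps(binarize_cohort(expr, signature, ...), signature)
}
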