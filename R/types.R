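#' Construct an expression matrix
#'
#' A genes-by-samples numeric matrix with unique row (gene) and column
#' (sample) identifiers and a declared measurement scale. Count-scale
#' matrices hold raw sequencing read counts; log-scale matrices hold
#' log-transformed intensities or log-counts (e.g. microarray data).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene IDs) and colnames (sample IDs). `NA` entries are allowed
#'   and mean "not measured", never zero.
#' @param scale `"count"` or `"log"`. Count-scale values must be
#'   non-negative where observed.
#' @return An object of class `expr_matrix`: the numeric matrix with a
#'   `scale` attribute.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' em <- expression_matrix(m, scale = "count")
#' @export
expression_matrix <- function(values, scale = c("count", "log")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  if (scale == "count" && any(values < 0, na.rm = TRUE))
    stop("count-scale expression values must be non-negative")
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' Subset an expression matrix, keeping its class and scale
#'
#' Unlike base matrix subsetting, dimensions are never dropped: a one-gene
#' or one-sample subset is still an `expr_matrix`.
#'
#' @param x An [expression_matrix()].
#' @param i,j Row (gene) and column (sample) indices.
#' @param ... Unused.
#' @param drop Ignored; kept `FALSE`.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, drop = FALSE]
  attr(out, "scale") <- attr(x, "scale")
  class(out) <- class(x)
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' Construct a clinical survival table
#'
#' Per-sample time-to-event data: follow-up time in months, a binary event
#' indicator (1 = relapse/death observed, 0 = right-censored), and optional
#' covariate columns (numeric or factor). The endpoint (RFS, DFS or OS) is
#' declared by a tag so that downstream reports can state what was analysed.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param time Non-negative survival times in months.
#' @param event Event indicators, each 0 or 1.
#' @param covariates Optional data.frame of extra columns (age, sex, stage,
#'   mutation flags, ...). Character columns are converted to factors.
#' @param endpoint One of `"RFS"`, `"DFS"`, `"OS"`.
#' @return A data.frame of class `clinical_table` with columns `sample_id`,
#'   `time`, `event` plus any covariates, and an `endpoint` attribute.
#' @export
clinical_table <- function(sample_id, time, event, covariates = NULL,
                           endpoint = c("RFS", "DFS", "OS")) {
  endpoint <- match.arg(endpoint)
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (length(time) != n || length(event) != n)
    stop("sample_id, time and event must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad_t <- which(!is.finite(time) | time < 0)
  if (length(bad_t))
    stop("invalid survival time (missing or negative) at row ", bad_t[1])
  bad_e <- which(!(event %in% c(0, 1)))
  if (length(bad_e))
    stop("event indicator not in {0, 1} at row ", bad_e[1])
  out <- data.frame(sample_id = sample_id, time = as.numeric(time),
                    event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per sample")
    for (j in seq_along(covariates))
      if (is.character(covariates[[j]]))
        covariates[[j]] <- factor(covariates[[j]])
    out <- cbind(out, covariates)
  }
  attr(out, "endpoint") <- endpoint
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Bundle expression and clinical data for one cohort
#'
#' Joins an expression matrix and a clinical table on the intersection of
#' their sample IDs; samples present in only one of the two are dropped with
#' a message reporting how many.
#'
#' @param name Cohort label.
#' @param expression An [expression_matrix()].
#' @param clinical A [clinical_table()].
#' @param quiet Suppress the dropped-sample message.
#' @return A list of class `cohort_dataset` with elements `name`,
#'   `expression`, `clinical` and `n_dropped`.
#' @export
cohort_dataset <- function(name, expression, clinical, quiet = FALSE) {
  stopifnot(inherits(expression, "expr_matrix"),
            inherits(clinical, "clinical_table"))
  shared <- intersect(colnames(expression), clinical$sample_id)
  if (!length(shared))
    stop("cohort '", name, "': no samples shared between expression and clinical data")
  n_drop <- (ncol(expression) - length(shared)) +
    (nrow(clinical) - length(shared))
  if (n_drop > 0 && !quiet)
    message("cohort '", name, "': dropped ", n_drop,
            " sample(s) absent from one of the two tables")
  expr <- expression[, shared, drop = FALSE]
  attr(expr, "scale") <- attr(expression, "scale")
  class(expr) <- class(expression)
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  attr(clin, "endpoint") <- attr(clinical, "endpoint")
  class(clin) <- class(clinical)
  structure(list(name = name, expression = expr, clinical = clin,
                 n_dropped = n_drop),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> '%s': %d genes x %d samples, endpoint %s\n",
              x$name, nrow(x$expression), ncol(x$expression),
              attr(x$clinical, "endpoint")))
  invisible(x)
}

#' Construct a gene signature
#'
#' An ordered set of (gene, scoring direction, weight) entries. A gene with
#' direction `HIGH` scores 1 for patients whose expression lies above the
#' within-cohort median; a `LOW` gene scores 1 for patients at or below it.
#' Weights are positive and sum to `score_max`, so the maximum attainable
#' score (every gene at its scoring status) equals `score_max` exactly.
#'
#' @param gene_id Unique gene identifiers.
#' @param direction `"HIGH"` or `"LOW"` per gene.
#' @param weight Positive weights summing to `score_max` (checked to 1e-9).
#' @param entrez_id Optional Entrez Gene IDs.
#' @param score_max Target maximum score (default 50).
#' @return A data.frame of class `mps_signature` with a `score_max`
#'   attribute.
#' @seealso [mps_colon_signature()] for the published 16-gene signature.
#' @export
mps_signature <- function(gene_id, direction, weight, entrez_id = NA,
                          score_max = 50) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate signature genes: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  direction <- toupper(as.character(direction))
  if (!all(direction %in% c("HIGH", "LOW")))
    stop("direction must be HIGH or LOW")
  weight <- as.numeric(weight)
  if (any(!is.finite(weight) | weight <= 0))
    stop("signature weights must be positive")
  if (abs(sum(weight) - score_max) > 1e-9)
    stop(sprintf("signature weights sum to %.9f, expected score_max = %g",
                 sum(weight), score_max))
  out <- data.frame(gene_id = gene_id,
                    entrez_id = rep_len(as.character(entrez_id), length(gene_id)),
                    direction = direction, weight = weight,
                    stringsAsFactors = FALSE)
  attr(out, "score_max") <- score_max
  class(out) <- c("mps_signature", "data.frame")
  out
}

#' @export
print.mps_signature <- function(x, ...) {
  cat(sprintf("<mps_signature> %d genes (%d HIGH, %d LOW), max score %g\n",
              nrow(x), sum(x$direction == "HIGH"), sum(x$direction == "LOW"),
              attr(x, "score_max")))
  print.data.frame(x, ...)
  invisible(x)
}
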