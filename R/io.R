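#' Read a tab-delimited expression matrix
#'
#' Expects genes in rows: the first column holds gene IDs and the header row
#' holds sample IDs. Empty cells or `NA` are kept as missing values — they
#' are never silently turned into zeros.
#'
#' @param path File path.
#' @param scale Declared measurement scale, `"count"` or `"log"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("count", "log")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("'", path, "': no data rows")
  df <- utils::read.delim(text = lines, header = TRUE, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("'", path, "': malformed header (need gene ID column plus samples)")
  genes <- as.character(df[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene row(s): ", paste(dup, collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & col != "" & col != "NA" & is.na(parsed))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1]], genes[bad[1]], colnames(vals)[j]))
      vals[[j]] <- parsed
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix
#'
#' Tab-delimited, genes in rows; inverse of [read_expression_matrix()].
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param id_col Header label for the gene-ID column.
#' @export
write_expression_matrix <- function(x, path, id_col = "gene_id") {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Delimited text with a header row. Column names for the sample ID,
#' survival time (months) and event indicator are declared by the caller;
#' all remaining columns are kept as covariates (character columns become
#' factors). Validation failures report the offending row.
#'
#' @param path File path.
#' @param id_col,time_col,event_col Column names in the file.
#' @param endpoint Survival endpoint tag: `"RFS"`, `"DFS"` or `"OS"`.
#' @param sep Field separator (default tab; use "," for CSV).
#' @return A [clinical_table()].
#' @export
read_clinical_table <- function(path, id_col = "sample_id",
                                time_col = "time", event_col = "event",
                                endpoint = c("RFS", "DFS", "OS"), sep = "\t") {
  endpoint <- match.arg(endpoint)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c(id_col, time_col, event_col))
    if (!cl %in% colnames(df))
      stop("'", path, "': missing column '", cl, "'")
  time <- suppressWarnings(as.numeric(df[[time_col]]))
  bad <- which(is.na(time))
  if (length(bad))
    stop("missing or non-numeric survival time at row ", bad[1])
  covs <- df[, setdiff(colnames(df), c(id_col, time_col, event_col)),
             drop = FALSE]
  clinical_table(df[[id_col]], time, df[[event_col]],
                 covariates = if (ncol(covs)) covs else NULL,
                 endpoint = endpoint)
}

#' Write a clinical table
#' @param x A [clinical_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_clinical_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "clinical_table"))
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep only samples with strictly positive follow-up
#'
#' Samples recorded with zero follow-up time carry no survival information
#' and are removed before any analysis, mirroring the usual cohort-intake
#' filter (RFS/DFS > 0). The number of removed rows is reported.
#'
#' @param clinical A [clinical_table()].
#' @param quiet Suppress the removal message.
#' @return The filtered [clinical_table()]; a warning is raised if nothing
#'   survives the filter.
#' @export
filter_positive_survival <- function(clinical, quiet = FALSE) {
  stopifnot(inherits(clinical, "clinical_table"))
  keep <- clinical$time > 0
  n_rm <- sum(!keep)
  if (n_rm > 0 && !quiet)
    message("removed ", n_rm, " sample(s) with follow-up time <= 0")
  out <- clinical[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "endpoint") <- attr(clinical, "endpoint")
  class(out) <- class(clinical)
  if (nrow(out) == 0L)
    warning("no samples with positive follow-up remain")
  out
}

#' Read a signature file
#'
#' Accepts the TSV form (header `gene_id  entrez_id  direction  weight`) or
#' its JSON twin (an object with fields `score_max` and `entries`). Weights
#' are parsed from their decimal representation, so printed 3-decimal
#' weights round-trip exactly.
#'
#' @param path File path (`.json` files are parsed as JSON, anything else
#'   as TSV).
#' @return An [mps_signature()].
#' @export
read_signature <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    e <- obj$entries
    return(mps_signature(e$gene_id, e$direction, e$weight,
                         entrez_id = if (!is.null(e$entrez_id)) e$entrez_id else NA,
                         score_max = if (!is.null(obj$score_max)) obj$score_max else 50))
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_id", "direction", "weight")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("signature file missing column(s): ", paste(miss, collapse = ", "))
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w)) stop("non-numeric signature weight")
  mps_signature(df$gene_id, df$direction, w,
                entrez_id = if ("entrez_id" %in% colnames(df)) df$entrez_id else NA,
                score_max = sum(w))
}

#' Write a signature file
#'
#' Weights are written as fixed 3-decimal strings so that the printed file
#' is byte-stable and read/write round-trips are lossless at the published
#' precision. Learned signatures whose weights need more precision can
#' raise `digits`.
#'
#' @param signature An [mps_signature()].
#' @param path Output path; a `.json` extension selects the JSON twin.
#' @param digits Decimal places for TSV weights.
#' @export
write_signature <- function(signature, path, digits = 3) {
  stopifnot(inherits(signature, "mps_signature"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(score_max = attr(signature, "score_max"),
                entries = data.frame(gene_id = signature$gene_id,
                                     entrez_id = signature$entrez_id,
                                     direction = signature$direction,
                                     weight = signature$weight,
                                     stringsAsFactors = FALSE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    df <- data.frame(gene_id = signature$gene_id,
                     entrez_id = signature$entrez_id,
                     direction = signature$direction,
                     weight = formatC(signature$weight, format = "f",
                                      digits = digits),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' The published 16-gene mPS_colon signature
#'
#' Loads the packaged colon-cancer signature: 16 genes, 6 scored when
#' expression is above the cohort median (HIGH) and 10 when at or below it
#' (LOW), with weights summing to exactly 50.000.
#'
#' @return An [mps_signature()] with 16 entries.
#' @examples
#' sig <- mps_colon_signature()
#' sum(sig$weight)  # 50
#' @export
mps_colon_signature <- function() {
  read_signature(system.file("extdata", "mps_colon_signature.tsv",
                             package = "mpscolon", mustWork = TRUE))
}

#' Sizes of the published meta-analysis cohorts
#'
#' The eight public colorectal-cancer cohorts entering the prognostic
#' meta-analysis, with their accession numbers and patient counts
#' (1201 patients in total).
#'
#' @return A data.frame with columns `accession` and `n_patients`.
#' @export
meta_cohort_sizes <- function() {
  utils::read.delim(system.file("extdata", "meta_analysis_cohorts.tsv",
                                package = "mpscolon", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
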