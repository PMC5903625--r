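#' Construct an expression matrix
#'
#' A thin wrapper around a numeric feature-by-sample matrix that records
#' whether the values are raw aligned-nucleotide counts or per-sample
#' normalized fractions. All downstream statistics consume the normalized
#' form.
#'
#' @param values Numeric matrix, features (ORFs, KOs, families, ...) in rows,
#'   samples in columns. Row and column names are required.
#' @param mode Either `"raw"` (non-negative integer nucleotide counts) or
#'   `"normalized"` (each sample column sums to 1 unless all-zero).
#' @return A numeric matrix of class `expr_matrix` with a `mode` attribute.
#' @export
expression_matrix <- function(values, mode = c("raw", "normalized")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs row (feature) and column (sample) names")
  if (any(values < 0)) stopf("expression values must be non-negative")
  if (mode == "raw" && any(abs(values - round(values)) > 1e-9))
    stopf("raw mode requires integer nucleotide counts")
  if (mode == "normalized") {
    cs <- colSums(values)
    bad <- which(cs > 0 & abs(cs - 1) > 1e-8)
    if (length(bad))
      stopf("normalized columns must sum to 1; offending sample(s): %s",
            paste(colnames(values)[bad], collapse = ", "))
  }
  structure(values, mode = mode, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, mode = %s\n",
              nrow(x), ncol(x), attr(x, "mode")))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE],
                    4L), ...)
  invisible(x)
}

expr_mode <- function(x) attr(x, "mode") %||% "raw"

#' Per-sample normalization of an expression matrix
#'
#' Scales each gene by the total number of nucleotides mapped to ORFs of the
#' same sample, so every column of the result sums to 1. This is the only
#' normalization applied: no gene-length correction, so longer genes carry
#' proportionally more weight (see [count_aligned_nucleotides()] for an
#' optional per-kilobase mode).
#'
#' @param raw An `expr_matrix` in raw mode.
#' @return An `expr_matrix` in normalized mode.
#' @export
normalize_per_sample <- function(raw) {
  if (expr_mode(raw) != "raw")
    stopf("normalize_per_sample() expects a raw-mode matrix")
  totals <- colSums(raw)
  zero <- which(totals == 0)
  if (length(zero))
    stopf("sample(s) with no ORF-mapped nucleotides cannot be normalized: %s",
          paste(colnames(raw)[zero], collapse = ", "))
  expression_matrix(sweep(unclass(raw), 2L, totals, "/"), "normalized")
}

#' Aggregate feature rows of a normalized matrix by a grouping
#'
#' Sums member rows per group label. Features absent from the grouping (or
#' mapped to `NA`) are collected under `"unassigned"`, so per-sample column
#' sums are preserved exactly.
#'
#' @param norm A normalized `expr_matrix` (features x samples).
#' @param grouping Named character vector mapping feature id to group label
#'   (e.g. ORF id to KO, or ORF id to family).
#' @param drop_unassigned Drop the `"unassigned"` row from the result
#'   (default `FALSE`; note that dropping breaks column-sum conservation).
#' @return A group x sample `expr_matrix` in normalized mode; rows are the
#'   sorted group labels.
#' @export
aggregate_by <- function(norm, grouping, drop_unassigned = FALSE) {
  if (expr_mode(norm) != "normalized")
    stopf("aggregate_by() expects a normalized matrix")
  labels <- unname(grouping[rownames(norm)])
  labels[is.na(labels)] <- "unassigned"
  agg <- rowsum(unclass(norm), group = labels, reorder = TRUE)
  if (drop_unassigned) agg <- agg[rownames(agg) != "unassigned", , drop = FALSE]
  structure(agg, mode = "normalized",
            class = c("expr_matrix", "matrix", "array"))
}

#' @rdname aggregate_by
#' @param raw A raw-mode `expr_matrix` (counts are summed per group; used
#'   for KO-level read-count summaries feeding the iPath width export).
#' @export
aggregate_counts <- function(raw, grouping, drop_unassigned = FALSE) {
  if (expr_mode(raw) != "raw")
    stopf("aggregate_counts() expects a raw matrix")
  labels <- unname(grouping[rownames(raw)])
  labels[is.na(labels)] <- "unassigned"
  agg <- rowsum(unclass(raw), group = labels, reorder = TRUE)
  if (drop_unassigned) agg <- agg[rownames(agg) != "unassigned", , drop = FALSE]
  structure(agg, mode = "raw", class = c("expr_matrix", "matrix", "array"))
}

#' Write / read an expression matrix as TSV
#'
#' Feature rows, sample columns, header row, full precision.
#' @param x An `expr_matrix`.
#' @param path Output file.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param mode Matrix mode to stamp on the read result.
#' @export
read_expression_tsv <- function(path, mode = c("raw", "normalized")) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, match.arg(mode))
}
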