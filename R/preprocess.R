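## Expression-matrix ingestion and feature preparation. Everything stays
## sparse except the (small) per-classifier feature panel.

## Instrumentation: record the widest dense block ever materialized, so
## the sparse-path contract (never densify beyond cells x features) can
## be asserted from outside.
.sparse_audit <- new.env(parent = emptyenv())
.sparse_audit$peak_cols <- 0L

#' Sparse-densification audit
#'
#' The only place the package densifies data is the per-classifier
#' feature panel. `sparseAuditReset()` zeroes the record;
#' `sparseAuditPeak()` returns the largest number of columns densified
#' since the last reset.
#'
#' @return `sparseAuditPeak()`: integer column count.
#' @export
sparseAuditReset <- function() {
  .sparse_audit$peak_cols <- 0L
  invisible(NULL)
}

#' @rdname sparseAuditReset
#' @export
sparseAuditPeak <- function() .sparse_audit$peak_cols

auditDensified <- function(ncols) {
  if (ncols > .sparse_audit$peak_cols)
    .sparse_audit$peak_cols <- as.integer(ncols)
  invisible(NULL)
}

readIdColumn <- function(path, what) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = ""),
    error = function(e)
      ctStop("format_error", "cannot read %s file '%s': %s", what, path,
             conditionMessage(e)))
  tab
}

findMtxFile <- function(dir, base) {
  for (cand in file.path(dir, c(base, paste0(base, ".gz"))))
    if (file.exists(cand)) return(cand)
  ctStop("format_error", "'%s' not found in MTX directory '%s'", base, dir)
}

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported: a 10x-style MTX directory
#' (`matrix.mtx`, `features.tsv`, `barcodes.tsv`, optionally gzipped;
#' MatrixMarket coordinate format with 1-based indices) and a dense
#' CSV/TSV with an identifier header row and first column. Whatever the
#' on-disk orientation, the result is oriented cells x genes and stored
#' sparse, flagged as raw counts.
#'
#' @param path MTX directory or CSV file.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param orientation on-disk orientation: `"genes_by_cells"` (10x
#'   default) or `"cells_by_genes"`.
#' @return An [ExpressionMatrix-class] with `is_normalized = FALSE`.
#' @export
readExpression <- function(path, format = c("mtx_dir", "csv"),
                           orientation = c("genes_by_cells",
                                           "cells_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx_dir") {
    mm <- tryCatch(Matrix::readMM(findMtxFile(path, "matrix.mtx")),
                   error = function(e)
                     ctStop("format_error", "cannot parse matrix.mtx in '%s': %s",
                            path, conditionMessage(e)))
    feats <- readIdColumn(findMtxFile(path, "features.tsv"), "features")
    ## Column 2 carries the gene symbol in 10x exports; fall back to the
    ## first column for single-column files.
    gene_ids <- if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]]
    barcodes <- readIdColumn(findMtxFile(path, "barcodes.tsv"), "barcodes")[[1L]]
    n_row_ids <- if (orientation == "genes_by_cells") gene_ids else barcodes
    n_col_ids <- if (orientation == "genes_by_cells") barcodes else gene_ids
    if (nrow(mm) != length(n_row_ids) || ncol(mm) != length(n_col_ids))
      ctStop("format_error",
             "matrix is %d x %d but identifier files have %d and %d entries",
             nrow(mm), ncol(mm), length(n_row_ids), length(n_col_ids))
    if (orientation == "genes_by_cells") mm <- Matrix::t(mm)
    vals <- mm
    cells <- barcodes
    genes <- gene_ids
  } else {
    df <- tryCatch(
      utils::read.csv(path, header = TRUE, row.names = 1L,
                      check.names = FALSE),
      error = function(e)
        ctStop("format_error", "cannot parse CSV '%s': %s", path,
               conditionMessage(e)))
    m <- as.matrix(df)
    if (orientation == "genes_by_cells") m <- t(m)
    vals <- m
    cells <- rownames(m)
    genes <- colnames(m)
  }
  if (anyDuplicated(cells))
    ctStop("format_error", "duplicate cell identifiers (e.g. '%s')",
           cells[duplicated(cells)][1L])
  if (anyDuplicated(genes))
    ctStop("format_error", "duplicate gene identifiers (e.g. '%s')",
           genes[duplicated(genes)][1L])
  expressionMatrix(vals, cell_ids = cells, gene_ids = genes,
                   is_normalized = FALSE)
}

#' Library-size normalization
#'
#' Scales each cell to `scale_total` total counts, then applies
#' `log1p`. Zeros stay zeros, so the stored sparsity pattern is
#' unchanged. The standard single-cell "LogNormalize" recipe.
#'
#' @param m an [ExpressionMatrix-class] of raw counts.
#' @param scale_total target per-cell total (default 1e4).
#' @return The normalized [ExpressionMatrix-class] (`is_normalized = TRUE`).
#' @export
normalizeCounts <- function(m, scale_total = 1e4) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (isNormalized(m))
    ctStop("validity_error", "matrix is already normalized")
  assertScalarNumber(scale_total, "scale_total")
  if (scale_total <= 0)
    ctStop("validity_error", "scale_total must be positive")
  totals <- Matrix::rowSums(m@values)
  if (any(totals <= 0))
    ctStop("degenerate_cell_error", "all-zero cell(s): %s",
           paste(utils::head(rownames(m@values)[totals <= 0], 5L),
                 collapse = ", "))
  v <- Matrix::Diagonal(x = scale_total / totals) %*% m@values
  v <- as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m@values)
  new("ExpressionMatrix", values = v, is_normalized = TRUE)
}

#' Extract a classifier's feature panel as a dense matrix
#'
#' Returns the requested gene columns, in the requested order, densified
#' (this is the only densification in the package and is recorded by the
#' sparse audit). Genes absent from the matrix become zero-filled
#' columns, listed in `missing_features` and named in a warning.
#'
#' @param m a normalized [ExpressionMatrix-class].
#' @param features ordered character vector of gene symbols.
#' @return A [FeatureMatrix-class].
#' @export
extractFeatures <- function(m, features) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (!isNormalized(m))
    ctStop("validity_error",
           "features must be extracted from a normalized matrix")
  features <- as.character(features)
  idx <- match(features, colnames(m@values))
  if (all(is.na(idx)))
    ctStop("empty_overlap_error",
           "none of the %d requested features are present in the matrix",
           length(features))
  missing <- features[is.na(idx)]
  auditDensified(length(features))
  out <- matrix(0, nrow = nrow(m@values), ncol = length(features),
                dimnames = list(rownames(m@values), features))
  present <- !is.na(idx)
  out[, present] <- as.matrix(m@values[, idx[present], drop = FALSE])
  if (length(missing))
    ctWarn("missing_features_warning",
           "%d feature(s) absent from the matrix, zero-filled: %s",
           length(missing), paste(missing, collapse = ", "))
  new("FeatureMatrix", values = out, missing_features = missing)
}

#' Apply training-set standardization constants
#'
#' Per column: \eqn{z = (x - mean)/sd}, with the constants stored in the
#' classifier at training time.
#'
#' @param fm a [FeatureMatrix-class].
#' @param means,sds numeric vectors, one per feature column; `sds` must
#'   be strictly positive.
#' @return The standardized [FeatureMatrix-class].
#' @export
standardizeFeatures <- function(fm, means, sds) {
  stopifnot(is(fm, "FeatureMatrix"))
  k <- ncol(fm@values)
  if (length(means) != k || length(sds) != k)
    ctStop("shape_error",
           "means/sds have lengths %d/%d but the matrix has %d features",
           length(means), length(sds), k)
  if (any(!is.finite(sds)) || any(sds <= 0))
    ctStop("shape_error", "all sds must be positive and finite")
  z <- sweep(sweep(fm@values, 2L, means, "-"), 2L, sds, "/")
  new("FeatureMatrix", values = z, missing_features = fm@missing_features)
}
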