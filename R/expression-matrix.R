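#' Validate a cells x genes expression matrix
#'
#' Expression matrices throughout the package are plain numeric matrices with
#' cells as rows and genes as columns; `rownames()` carry cell identifiers and
#' `colnames()` carry gene identifiers. Values must be finite and
#' non-negative, and identifiers must be unique.
#'
#' @param x A numeric matrix, cells x genes, with dimnames.
#' @param require_names Require non-NULL row and column names (default TRUE).
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x, require_names = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix (cells x genes)")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("expression matrix contains NA or non-finite values")
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("expression matrix contains negative values (first at cell %d, gene %d)",
                 bad[1L], bad[2L]))
  }
  if (require_names) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("expression matrix must have cell (row) and gene (column) names")
    }
    if (anyDuplicated(rownames(x))) stop("duplicate cell identifiers")
    if (anyDuplicated(colnames(x))) stop("duplicate gene identifiers")
  }
  invisible(x)
}

#' Construct an expression matrix with default identifiers
#'
#' @param values Numeric matrix, cells x rows.
#' @param cell_ids,gene_ids Optional identifier vectors; autogenerated when
#'   absent and the matrix has no dimnames.
#' @return A validated cells x genes matrix.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(cell_ids)) rownames(values) <- cell_ids
  if (!is.null(gene_ids)) colnames(values) <- gene_ids
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cell_%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("gene_%d", seq_len(ncol(values)))
  }
  validate_expression_matrix(values)
  values
}
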