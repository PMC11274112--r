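#' Read an expression matrix from CSV, TSV or MatrixMarket files
#'
#' Dense CSV/TSV files carry a header row of gene identifiers and a first
#' column of cell identifiers (cells x genes on disk). MatrixMarket input
#' follows the cellranger layout: the `.mtx` file stores genes x columns
#' and is transposed on read, with `barcodes.tsv` (cell ids) and `genes.tsv`
#' (gene ids) sidecars next to it.
#'
#' @param path Path to the matrix file.
#' @param fmt One of `"csv"`, `"tsv"`, `"mtx"`. Guessed from the file
#'   extension when missing.
#' @param transpose For dense input whose rows are genes rather than cells,
#'   set TRUE to transpose after reading. Never guessed from the data.
#' @return A validated cells x genes numeric matrix.
#' @export
read_expr_matrix <- function(path, fmt = c("csv", "tsv", "mtx"), transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (length(fmt) > 1L) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("csv", "tsv", "mtx")) ext else "csv"
  }
  fmt <- match.arg(fmt, c("csv", "tsv", "mtx"))

  if (fmt == "mtx") {
    x <- .read_mtx_triplet(path)
  } else {
    sep <- if (fmt == "tsv") "\t" else ","
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)))
    )
    bad <- which(!vapply(df, is.numeric, logical(1L)))
    if (length(bad)) {
      stop(sprintf("non-numeric values in column '%s' of %s", names(df)[bad[1L]], path))
    }
    x <- as.matrix(df)
    if (transpose) x <- t(x)
  }
  validate_expression_matrix(x)
  x
}

.read_mtx_triplet <- function(path) {
  dir <- dirname(path)
  barcodes_path <- file.path(dir, "barcodes.tsv")
  genes_path <- file.path(dir, "genes.tsv")
  if (!file.exists(barcodes_path) || !file.exists(genes_path)) {
    stop(sprintf("mtx sidecars barcodes.tsv / genes.tsv not found alongside %s", path))
  }
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop(sprintf("failed to parse %s: %s", path, conditionMessage(e))))
  barcodes <- readLines(barcodes_path)
  genes_tab <- utils::read.table(genes_path, sep = "\t", stringsAsFactors = FALSE)
  gene_ids <- genes_tab[[1L]]
  if (nrow(m) != length(gene_ids) || ncol(m) != length(barcodes)) {
    stop(sprintf("mtx dimensions (%d x %d) do not match genes (%d) x barcodes (%d)",
                 nrow(m), ncol(m), length(gene_ids), length(barcodes)))
  }
  # cellranger stores genes x cells; package orientation is cells x genes
  x <- t(as.matrix(m))
  dimnames(x) <- list(barcodes, gene_ids)
  x
}

#' Write an expression matrix to CSV, TSV or MatrixMarket files
#'
#' Inverse of [read_expr_matrix()]: dense output has the header row of gene
#' ids and a leading cell-id column; mtx output writes the matrix transposed
#' (genes x cells) with `barcodes.tsv` and `genes.tsv` sidecars.
#'
#' @param x Cells x genes matrix.
#' @param path Output path.
#' @param fmt One of `"csv"`, `"tsv"`, `"mtx"`; guessed from the extension
#'   when missing.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(x, path, fmt = c("csv", "tsv", "mtx")) {
  validate_expression_matrix(x)
  if (length(fmt) > 1L) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("csv", "tsv", "mtx")) ext else "csv"
  }
  fmt <- match.arg(fmt, c("csv", "tsv", "mtx"))
  if (fmt == "mtx") {
    dir <- dirname(path)
    Matrix::writeMM(methods::as(Matrix::Matrix(t(x), sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(x), file.path(dir, "barcodes.tsv"))
    utils::write.table(data.frame(colnames(x), colnames(x)),
                       file.path(dir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (fmt == "tsv") "\t" else ","
    df <- data.frame(cell_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
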