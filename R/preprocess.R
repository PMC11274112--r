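#' Library-size normalization
#'
#' Rescales every cell so that all cells share the same total expression.
#' The common total is the median of the original per-cell totals, which
#' keeps values on the scale of the input counts; gene proportions within a
#' cell are unchanged. Cells with zero total are an error: quality filtering
#' (empty droplets, empty cells) belongs upstream of normalization.
#'
#' @param x Cells x genes matrix.
#' @return Normalized matrix of the same shape.
#' @export
library_size_normalize <- function(x) {
  validate_expression_matrix(x, require_names = FALSE)
  totals <- rowSums(x)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)[1L]
    stop(sprintf("cell %d has zero total expression; filter empty cells before normalizing", bad))
  }
  target <- stats::median(totals)
  x * (target / totals)
}

#' Elementwise variance-stabilizing transform
#'
#' @param x Cells x genes non-negative matrix.
#' @param kind `"none"`, `"sqrt"` or `"log1p"`. Both transforms are monotone
#'   and zero-preserving; square root is the usual choice for library-size
#'   normalized counts, log1p for data on a wider dynamic range.
#' @return Transformed matrix.
#' @export
transform_expression <- function(x, kind = c("none", "sqrt", "log1p")) {
  kind <- match.arg(kind)
  validate_expression_matrix(x, require_names = FALSE)
  switch(kind,
         none = x,
         sqrt = sqrt(x),
         log1p = log1p(x))
}

#' Select highly variable genes by dispersion percentile
#'
#' Keeps genes whose dispersion statistic is at or above the given percentile
#' of all genes. The dispersion statistic is the per-gene variance computed
#' on the matrix as passed (normalize/transform first if desired); the
#' statistic used is recorded in the `hvg` attribute of the result so
#' alternative dispersions can be added without changing the contract.
#'
#' @param x Cells x genes matrix with at least 2 cells.
#' @param percentile Percentile cut in \[0, 100\]; 0 retains all genes.
#' @return Column-subset matrix with attribute `hvg = list(statistic,
#'   percentile, threshold)`.
#' @export
select_hvg <- function(x, percentile) {
  validate_expression_matrix(x, require_names = FALSE)
  if (nrow(x) < 2L) stop("at least 2 cells are required to estimate gene dispersion")
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile < 0 || percentile > 100) {
    stop("percentile must be a single value in [0, 100]")
  }
  disp <- apply(x, 2L, stats::var)
  threshold <- stats::quantile(disp, probs = percentile / 100, names = FALSE, type = 7)
  keep <- disp >= threshold
  out <- x[, keep, drop = FALSE]
  attr(out, "hvg") <- list(statistic = "variance", percentile = percentile,
                           threshold = threshold, n_selected = sum(keep))
  out
}
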