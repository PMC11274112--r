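#' First Wasserstein (Earth Mover's) distance between two samples
#'
#' Computed as the integral of the absolute difference between the two
#' empirical cumulative distribution functions over the pooled sorted
#' support. For equal-sized samples this equals the mean absolute
#' difference of the sorted values.
#'
#' @param u,v Non-empty numeric sample vectors.
#' @return Non-negative distance.
#' @export
emd_1d <- function(u, v) {
  if (length(u) == 0L || length(v) == 0L) stop("samples must be non-empty")
  if (anyNA(u) || anyNA(v)) stop("samples must not contain NA")
  z <- sort(c(u, v))
  m <- length(z)
  if (m < 2L) return(0)
  deltas <- diff(z)
  su <- sort(u); sv <- sort(v)
  grid <- z[-m]
  cu <- findInterval(grid, su) / length(u)
  cv <- findInterval(grid, sv) / length(v)
  sum(abs(cu - cv) * deltas)
}

#' Signed EMD differential-expression score table (one vs rest)
#'
#' For every gene and every cluster, the first Wasserstein distance between
#' the gene's in-cluster and out-of-cluster expression distributions, signed
#' by the direction of the mean difference: positive when the cluster mean
#' exceeds the rest, negative when below, zero when equal. EMD makes no
#' distributional assumption, which suits the multimodal per-cluster
#' distributions of imputed single-cell data better than mean collapsing.
#'
#' @param d_imp Cells x genes (typically imputed) expression matrix.
#' @param cluster_labels Per-cell cluster labels; at least 2 clusters, none
#'   covering all cells.
#' @return Genes x clusters numeric matrix of signed scores.
#' @export
emd_score_table <- function(d_imp, cluster_labels) {
  validate_expression_matrix(d_imp, require_names = FALSE)
  if (length(cluster_labels) != nrow(d_imp)) {
    stop("cluster_labels length must equal number of cells")
  }
  labs <- as.character(cluster_labels)
  clusters <- sort(unique(labs))
  if (length(clusters) < 2L) stop("need at least 2 clusters (one cluster would leave an empty rest)")
  scores <- matrix(0, ncol(d_imp), length(clusters),
                   dimnames = list(colnames(d_imp), clusters))
  for (cl in clusters) {
    in_cl <- labs == cl
    for (g in seq_len(ncol(d_imp))) {
      u <- d_imp[in_cl, g]
      v <- d_imp[!in_cl, g]
      s <- sign(mean(u) - mean(v))
      scores[g, cl] <- if (s == 0) 0 else emd_1d(u, v) * s
    }
  }
  scores
}

#' Marker over-smoothing evaluation via Tukey HSD
#'
#' Tests whether imputation kept each marker gene differentially expressed
#' in its true phenotype(s) without smearing it into others. A marker is
#' called "differentially expressed" in a phenotype when Tukey's honestly
#' significant difference test (on a one-way fit of expression by phenotype,
#' family-wise error controlled at `alpha`) shows the phenotype's mean
#' significantly above the other phenotypes — all of them under
#' `rule = "all"` (strict), more than half under `rule = "majority"` — and
#' the phenotype's mean is at least `fold_change` times the mean of the
#' remaining cells. The resulting binary marker x phenotype call matrix is
#' compared against the supplied truth map to yield precision, recall and
#' F1 over all marker-phenotype pairs. Diffusion smooths expression toward
#' approximate normality within phenotypes, which is what makes the Tukey
#' test applicable post-imputation.
#'
#' @param d_imp Cells x genes imputed expression matrix with gene names.
#' @param phenotype_labels Per-cell phenotype labels (>= 2 phenotypes, each
#'   with >= 2 cells).
#' @param markers Named list: marker gene -> character vector of phenotypes
#'   in which it is truly differentially expressed.
#' @param fold_change Minimum mean fold change vs the rest (default 2).
#' @param alpha Family-wise error level for Tukey HSD (default 0.05).
#' @param rule `"all"` (significant above every other phenotype, default)
#'   or `"majority"` (above more than half).
#' @return List of class `marker_eval`: `calls` and `truth` (binary
#'   marker x phenotype matrices), `precision`, `recall`, `f1`, `confusion`
#'   (tp/fp/fn/tn).
#' @export
marker_overspread_eval <- function(d_imp, phenotype_labels, markers,
                                   fold_change = 2, alpha = 0.05,
                                   rule = c("all", "majority")) {
  rule <- match.arg(rule)
  validate_expression_matrix(d_imp, require_names = FALSE)
  if (is.null(colnames(d_imp))) stop("d_imp must have gene names")
  if (length(phenotype_labels) != nrow(d_imp)) {
    stop("phenotype_labels length must equal number of cells")
  }
  missing_markers <- setdiff(names(markers), colnames(d_imp))
  if (length(missing_markers)) {
    stop("marker gene(s) absent from matrix: ", paste(missing_markers, collapse = ", "))
  }
  labs <- as.character(phenotype_labels)
  phenos <- sort(unique(labs))
  if (length(phenos) < 2L) stop("need at least 2 phenotypes")
  if (any(table(labs) < 2L)) stop("every phenotype needs at least 2 cells")

  # internal safe level names so Tukey's "A-B" rownames parse unambiguously
  safe <- stats::setNames(sprintf("p%03d", seq_along(phenos)), phenos)
  f <- factor(safe[labs], levels = safe)

  calls <- matrix(0L, length(markers), length(phenos),
                  dimnames = list(names(markers), phenos))
  eps <- 1e-9
  for (mk in names(markers)) {
    expr <- d_imp[, mk]
    fit <- stats::aov(expr ~ f, data = data.frame(expr = expr, f = f))
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$f
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    means <- tapply(expr, f, mean)
    for (p in phenos) {
      sp <- safe[[p]]
      others <- setdiff(unname(safe), sp)
      above <- vapply(others, function(q) {
        row <- which((cmp[, 1L] == sp & cmp[, 2L] == q) |
                     (cmp[, 1L] == q & cmp[, 2L] == sp))[1L]
        sig <- is.finite(tk[row, "p adj"]) && tk[row, "p adj"] < alpha
        sig && means[[sp]] > means[[q]]
      }, logical(1L))
      n_required <- if (rule == "all") length(others) else floor(length(others) / 2) + 1L
      mean_rest <- mean(expr[f != sp])
      fc <- (means[[sp]] + eps) / (mean_rest + eps)
      calls[mk, p] <- as.integer(sum(above) >= n_required && fc >= fold_change)
    }
  }

  truth <- matrix(0L, length(markers), length(phenos),
                  dimnames = dimnames(calls))
  for (mk in names(markers)) {
    unknown <- setdiff(markers[[mk]], phenos)
    if (length(unknown)) {
      stop(sprintf("truth map for '%s' names unknown phenotype(s): %s",
                   mk, paste(unknown, collapse = ", ")))
    }
    truth[mk, markers[[mk]]] <- 1L
  }

  tp <- sum(calls == 1L & truth == 1L)
  fp <- sum(calls == 1L & truth == 0L)
  fn <- sum(calls == 0L & truth == 1L)
  tn <- sum(calls == 0L & truth == 0L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)

  structure(
    list(calls = calls, truth = truth,
         precision = precision, recall = recall, f1 = f1,
         confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
         params = list(fold_change = fold_change, alpha = alpha, rule = rule)),
    class = "marker_eval"
  )
}

#' @export
print.marker_eval <- function(x, ...) {
  cat(sprintf("<marker_eval> %d markers x %d phenotypes | precision=%.3f recall=%.3f f1=%.3f\n",
              nrow(x$calls), ncol(x$calls), x$precision, x$recall, x$f1))
  invisible(x)
}
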