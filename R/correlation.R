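#' Ensemble correlation statistics
#'
#' The two correlation views of a cell ensemble's data matrix X (n cells x
#' m genes): the cell-cell matrix R(S^k, S^l) correlating cell state
#' vectors across genes, and the gene-gene matrix R(g_i, g_j) correlating
#' gene vectors across cells. As an ensemble approaches a critical state
#' transition the cell-cell average falls (cells diversify in the
#' flattening attractor basin) while the average absolute gene-gene
#' correlation rises (cells align along the exit reaction coordinate).
#'
#' Pearson correlation is undefined for a zero-variance vector; all pairs
#' involving such a vector are set to `NA`, excluded from averages, and
#' counted as dropped.
#'
#' @param x an [expression_matrix()].
#' @param genes gene selection; default all target (non-control) genes.
#' @param cells cell selection; default all cells.
#' @return a symmetric correlation matrix with unit diagonal (`NA` rows
#'   and columns for zero-variance vectors).
#' @seealso [correlation_summary()], [compute_ic()]
#' @export
cell_cell_correlation <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- .resolve_ids(genes, gene_ids(x), default = target_genes(x))
  cells <- .resolve_ids(cells, cell_ids(x))
  if (length(genes) < 3L)
    stop("need at least 3 genes to correlate cell state vectors")
  .pairwise_pearson(t(x$values[cells, genes, drop = FALSE]))
}

#' @rdname cell_cell_correlation
#' @export
gene_gene_correlation <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- .resolve_ids(genes, gene_ids(x), default = target_genes(x))
  cells <- .resolve_ids(cells, cell_ids(x))
  if (length(cells) < 3L)
    stop("need at least 3 cells to correlate gene vectors")
  .pairwise_pearson(x$values[cells, genes, drop = FALSE])
}

# Pearson correlation between the columns of m. Zero-variance columns are
# made fully NA (diagonal included) so averages skip every pair involving
# them; well-defined columns keep a unit diagonal.
.pairwise_pearson <- function(m) {
  sds <- apply(m, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  degen <- !is.finite(sds) | sds == 0
  r[degen, ] <- NA_real_
  r[, degen] <- NA_real_
  diag(r)[!degen] <- 1
  r
}

.offdiag_stats <- function(r, absolute = FALSE) {
  v <- r[upper.tri(r)]
  if (absolute) v <- abs(v)
  list(mean = mean(v, na.rm = TRUE), dropped = sum(is.na(v)),
       n_pairs = sum(!is.na(v)))
}

#' Summarize both correlation views of an ensemble
#'
#' Computes the cell-cell and gene-gene Pearson matrices and the two
#' averages entering the critical-transition index: the signed mean
#' off-diagonal cell-cell correlation and the mean absolute off-diagonal
#' gene-gene correlation. The signed gene-gene mean is also reported as a
#' diagnostic.
#'
#' @inheritParams cell_cell_correlation
#' @return an object of class `correlation_summary` with elements
#'   `cell_cell_matrix`, `gene_gene_matrix`, `mean_cell_cell`,
#'   `mean_abs_gene_gene`, `mean_gene_gene`, `n_cells`, `n_genes`,
#'   `dropped_pairs` (per view).
#' @export
correlation_summary <- function(x, genes = NULL, cells = NULL) {
  cc <- cell_cell_correlation(x, genes = genes, cells = cells)
  gg <- gene_gene_correlation(x, genes = genes, cells = cells)
  cc_s <- .offdiag_stats(cc)
  gg_s <- .offdiag_stats(gg, absolute = TRUE)
  if (cc_s$n_pairs == 0L || gg_s$n_pairs == 0L)
    stop("degenerate ensemble: all correlation pairs dropped")
  structure(list(cell_cell_matrix = cc,
                 gene_gene_matrix = gg,
                 mean_cell_cell = cc_s$mean,
                 mean_abs_gene_gene = gg_s$mean,
                 mean_gene_gene = .offdiag_stats(gg)$mean,
                 n_cells = nrow(cc), n_genes = nrow(gg),
                 dropped_pairs = c(cell = cc_s$dropped,
                                   gene = gg_s$dropped)),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(paste0("correlation_summary: %d cells x %d genes\n",
                     "  <R(cell,cell)>   = %.4f\n",
                     "  <|R(gene,gene)|> = %.4f\n"),
              x$n_cells, x$n_genes, x$mean_cell_cell, x$mean_abs_gene_gene))
  if (any(x$dropped_pairs > 0))
    cat(sprintf("  dropped pairs: %d cell, %d gene\n",
                x$dropped_pairs[["cell"]], x$dropped_pairs[["gene"]]))
  invisible(x)
}

#' Per-cell coefficient of variation
#'
#' A cell-specific dispersion descriptor: the population standard
#' deviation over the mean of a cell's expression values across genes.
#' Because log-scale expression can be negative, the whole matrix is first
#' shifted by a constant that puts its global minimum at +1; the shift is
#' returned as an attribute. The CV has no direct physical meaning; it
#' exposes how dispersed each cell's profile is relative to its peers in a
#' fixed positive affine frame.
#'
#' @inheritParams cell_cell_correlation
#' @return named numeric vector of CVs, one per cell, with attribute
#'   `shift`.
#' @export
per_cell_cv <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- .resolve_ids(genes, gene_ids(x), default = target_genes(x))
  cells <- .resolve_ids(cells, cell_ids(x))
  v <- x$values[cells, genes, drop = FALSE]
  shift <- 1 - min(v)
  v <- v + shift
  mu <- rowMeans(v)
  if (any(mu <= 0)) stop("cell mean non-positive after shift")
  pop_sd <- sqrt(rowMeans(sweep(v, 1L, mu)^2))
  structure(pop_sd / mu, shift = shift)
}

#' Bulk-profile dissimilarity with gene-resampling uncertainty
#'
#' Dissimilarity between two expression profiles as `1 - R` (R = Pearson
#' correlation over all genes), with a standard deviation estimated by
#' recomputing `1 - R` on random gene subsets: per resample one subset of
#' `ceiling(gene_fraction * m)` genes is drawn and applied to both
#' profiles.
#'
#' @param a,b numeric profile vectors of equal length >= 10.
#' @param gene_fraction fraction of genes per resample, in (0, 1]
#'   (default 0.3).
#' @param n_resamples number of random subsets (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param max_redraws redraw cap per resample when a subset has zero
#'   variance in either profile.
#' @return list with `dissimilarity` (point estimate on all genes), `sd`
#'   (resampling standard deviation) and `n_resamples`.
#' @export
profile_dissimilarity <- function(a, b, gene_fraction = 0.3,
                                  n_resamples = 10000, seed = NULL,
                                  max_redraws = 100) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (length(a) < 10L) stop("profiles must have length >= 10")
  if (gene_fraction <= 0 || gene_fraction > 1)
    stop("gene_fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- length(a)
  size <- ceiling(gene_fraction * m)
  point <- 1 - stats::cor(a, b)
  vals <- numeric(n_resamples)
  for (i in seq_len(n_resamples)) {
    for (attempt in seq_len(max_redraws + 1L)) {
      idx <- sample.int(m, size)
      if (stats::sd(a[idx]) > 0 && stats::sd(b[idx]) > 0) break
      if (attempt > max_redraws)
        stop("could not draw a gene subset with non-zero variance")
    }
    vals[i] <- 1 - stats::cor(a[idx], b[idx])
  }
  list(dissimilarity = point, sd = stats::sd(vals),
       n_resamples = n_resamples)
}
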