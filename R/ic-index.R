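#' Critical-state-transition index I_C
#'
#' For an ensemble of n cells measured over m genes,
#' `I_C = <|R(g_i, g_j)|> / <R(S^k, S^l)>`: the mean absolute gene-gene
#' Pearson correlation divided by the mean (signed) cell-cell Pearson
#' correlation. Around a stable attractor, symmetric stochastic
#' fluctuations keep gene-gene correlations near zero and cell-cell
#' correlations high, so I_C stays near its baseline; as the attractor
#' destabilizes toward a tipping point, cells diversify (denominator
#' falls) and align along the exit direction (numerator rises), so I_C
#' increases toward a maximum at the critical transition. Only the change
#' of I_C along a time course carries meaning, not its absolute value.
#'
#' The standard error is estimated by bootstrap over cells (the sampling
#' unit of the ensemble): cells are resampled with replacement, the index
#' recomputed, and the standard deviation over replicates reported.
#'
#' @param x an [expression_matrix()].
#' @param cells cell selection defining the ensemble; default all cells.
#' @param genes gene selection; default all target (non-control) genes.
#' @param B_sem number of bootstrap replicates for the SEM (default 200;
#'   0 skips the bootstrap and reports `NA`).
#' @param seed optional integer seed for the bootstrap.
#' @param group label attached to the result (e.g. a time point).
#' @return an object of class `ic_result`: list with `ic`, `sem`, `group`,
#'   `n_cells`, `n_genes` and `components` (the [correlation_summary()]).
#' @export
compute_ic <- function(x, cells = NULL, genes = NULL, B_sem = 200,
                       seed = NULL, group = "all") {
  comp <- correlation_summary(x, genes = genes, cells = cells)
  if (comp$mean_cell_cell <= 0)
    stop("denominator non-positive: cell ensemble has no common orientation")
  ic <- comp$mean_abs_gene_gene / comp$mean_cell_cell

  sem <- NA_real_
  if (B_sem > 0) {
    if (!is.null(seed)) set.seed(seed)
    cells_all <- .resolve_ids(cells, cell_ids(x))
    n <- length(cells_all)
    reps <- rep(NA_real_, B_sem)
    for (b in seq_len(B_sem)) {
      take <- x$values[cells_all[sample.int(n, n, replace = TRUE)], ,
                       drop = FALSE]
      rownames(take) <- sprintf("bs%d", seq_len(n))
      reps[b] <- tryCatch(.ic_of_matrix(take, genes, x), error = function(e)
        NA_real_)
    }
    sem <- stats::sd(reps, na.rm = TRUE)
  }

  structure(list(ic = ic, sem = sem, group = group,
                 n_cells = comp$n_cells, n_genes = comp$n_genes,
                 components = comp),
            class = "ic_result")
}

# I_C of a bare values matrix (cells x genes); NA when the denominator is
# non-positive. `genes` is resolved against the parent ExpressionMatrix.
.ic_of_matrix <- function(values, genes, parent) {
  genes <- .resolve_ids(genes, gene_ids(parent),
                        default = target_genes(parent))
  v <- values[, genes, drop = FALSE]
  cc <- .offdiag_stats(.pairwise_pearson(t(v)))
  gg <- .offdiag_stats(.pairwise_pearson(v), absolute = TRUE)
  if (cc$n_pairs == 0L || gg$n_pairs == 0L || cc$mean <= 0) return(NA_real_)
  gg$mean / cc$mean
}

#' @export
print.ic_result <- function(x, ...) {
  cat(sprintf("I_C [%s] = %.4f (SEM %.4f; %d cells, %d genes)\n",
              x$group, x$ic, x$sem, x$n_cells, x$n_genes))
  invisible(x)
}

#' I_C along a time course of grouped ensembles
#'
#' Splits the cells by metadata keys (time point, treatment, sorted
#' fraction), computes [compute_ic()] per group with one shared gene
#' subset, and returns a tidy table ordered by time point. Groups that are
#' too small or whose cell-cell mean is non-positive are skipped with a
#' message, never silently.
#'
#' @inheritParams compute_ic
#' @param group_by metadata column names to group cells by (subset of
#'   `time_point`, `treatment`, `fraction`).
#' @param min_cells minimum ensemble size per group (default 10).
#' @return data.frame with the grouping columns plus `n_cells`, `n_genes`,
#'   `mean_cell_cell`, `mean_abs_gene_gene`, `ic`, `sem`; the per-group
#'   `ic_result` objects are attached as attribute `"results"`.
#' @export
ic_timecourse <- function(x, group_by = "time_point", genes = NULL,
                          min_cells = 10, B_sem = 200, seed = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  bad <- setdiff(group_by, names(x$cell_meta))
  if (length(bad)) stop("unknown metadata key(s): ", paste(bad, collapse = ", "))
  keys <- x$cell_meta[group_by]
  split_idx <- split(seq_len(nrow(x$values)),
                     interaction(keys, drop = TRUE, lex.order = TRUE,
                                 sep = " / "))
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); results <- list()
  for (g in names(split_idx)) {
    idx <- split_idx[[g]]
    if (length(idx) < min_cells) {
      message("group '", g, "' skipped: only ", length(idx),
              " cells (minimum ", min_cells, ")")
      next
    }
    res <- tryCatch(
      compute_ic(x, cells = cell_ids(x)[idx], genes = genes,
                 B_sem = B_sem, group = g),
      error = function(e) {
        message("group '", g, "' skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    results[[g]] <- res
    meta <- x$cell_meta[idx[1L], group_by, drop = FALSE]
    rows[[g]] <- cbind(meta,
                       data.frame(n_cells = res$n_cells,
                                  n_genes = res$n_genes,
                                  mean_cell_cell = res$components$mean_cell_cell,
                                  mean_abs_gene_gene =
                                    res$components$mean_abs_gene_gene,
                                  ic = res$ic, sem = res$sem))
  }
  if (!length(rows)) stop("no group satisfied the preconditions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if ("time_point" %in% group_by)
    out <- out[order(out$time_point), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Permutation significance of an elevated I_C
#'
#' In data with no gene-gene coupling and no cell diversification beyond
#' the gene marginals, I_C cannot rise above its randomized baseline. The
#' null is built by independently permuting each gene's values across the
#' cells of the ensemble, which destroys gene-gene and structured
#' cell-cell correlation while preserving each gene's marginal
#' distribution. The test statistic is `log I_C`, one-sided: larger
#' values (the direction the index moves toward a critical transition)
#' are more extreme. The p-value uses the add-one correction
#' `p = (1 + #[null >= observed]) / (1 + B)` and is therefore
#' conservative.
#'
#' @inheritParams compute_ic
#' @param B number of permutation replicates (minimum 99; default 199).
#' @param max_redraws cap on redraws of degenerate permuted replicates.
#' @return an object of class `null_distribution`: list with `observed`
#'   (the statistic), `ic`, `null_values`, `p_value`, `scheme`, `seed`,
#'   `B`.
#' @export
permutation_null <- function(x, cells = NULL, genes = NULL, B = 199,
                             seed = NULL, max_redraws = 100) {
  if (B < 99) stop("B must be at least 99")
  res <- compute_ic(x, cells = cells, genes = genes, B_sem = 0)
  obs <- log(res$ic)
  if (!is.null(seed)) set.seed(seed)
  cells_all <- .resolve_ids(cells, cell_ids(x))
  v <- x$values[cells_all, , drop = FALSE]
  n <- nrow(v)
  null_values <- numeric(B)
  for (b in seq_len(B)) {
    stat <- NA_real_
    for (attempt in seq_len(max_redraws + 1L)) {
      perm <- apply(v, 2L, function(col) col[sample.int(n)])
      rownames(perm) <- rownames(v)
      ic_b <- .ic_of_matrix(perm, genes, x)
      if (is.finite(ic_b) && ic_b > 0) {
        stat <- log(ic_b)
        break
      }
      if (attempt > max_redraws)
        stop("permutation redraw cap exhausted (degenerate replicates)")
    }
    null_values[b] <- stat
  }
  structure(list(observed = obs, ic = res$ic, null_values = null_values,
                 p_value = (1 + sum(null_values >= obs)) / (1 + B),
                 scheme = "per-gene permutation across cells",
                 seed = seed, B = B),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(paste0("permutation null (%s, B = %d)\n",
                     "  I_C = %.4f, log I_C = %.4f, p = %.4g\n"),
              x$scheme, x$B, x$ic, x$observed, x$p_value))
  invisible(x)
}

#' Robustness of I_C to random gene subsampling
#'
#' Recomputes I_C and its two components on random gene subsets of given
#' sizes, drawn without replacement. When the genes carry a shared
#' transition signal, the spread of I_C across draws shrinks as the
#' subset grows, so larger panels give more stable index estimates.
#'
#' @inheritParams compute_ic
#' @param sizes integer vector of subset sizes (each <= number of
#'   candidate genes; sizes below 3 are skipped with a warning).
#' @param n_draws random subsets per size (>= 1).
#' @return data.frame with columns `size`, `draw`, `ic`, `mean_cell_cell`,
#'   `mean_abs_gene_gene`; per-size mean and sd of I_C are attached as
#'   attribute `"summary"`.
#' @export
gene_subsample_robustness <- function(x, sizes, n_draws = 20, cells = NULL,
                                      genes = NULL, seed = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (n_draws < 1) stop("n_draws must be >= 1")
  pool <- .resolve_ids(genes, gene_ids(x), default = target_genes(x))
  if (any(sizes > length(pool)))
    stop("subset size exceeds the ", length(pool), " candidate genes")
  small <- sizes < 3
  if (any(small)) {
    warning("size(s) below 3 skipped: ", paste(sizes[small], collapse = ", "))
    sizes <- sizes[!small]
  }
  if (!length(sizes)) stop("no usable subset size")
  cells_all <- .resolve_ids(cells, cell_ids(x))
  v <- x$values[cells_all, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(sizes) * n_draws)
  i <- 0L
  for (s in sizes) {
    for (d in seq_len(n_draws)) {
      sub <- sample(pool, s)
      cc <- .offdiag_stats(.pairwise_pearson(t(v[, sub, drop = FALSE])))
      gg <- .offdiag_stats(.pairwise_pearson(v[, sub, drop = FALSE]),
                           absolute = TRUE)
      ic <- if (cc$n_pairs > 0L && gg$n_pairs > 0L && cc$mean > 0)
        gg$mean / cc$mean else NA_real_
      if (is.na(ic))
        warning("size ", s, " draw ", d, ": degenerate subset, I_C is NA")
      i <- i + 1L
      rows[[i]] <- data.frame(size = s, draw = d, ic = ic,
                              mean_cell_cell = cc$mean,
                              mean_abs_gene_gene = gg$mean)
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$size), function(df)
    data.frame(size = df$size[1L], mean_ic = mean(df$ic, na.rm = TRUE),
               sd_ic = stats::sd(df$ic, na.rm = TRUE))))
  rownames(agg) <- NULL
  attr(out, "summary") <- agg[order(agg$size), , drop = FALSE]
  out
}
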