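#' Principal-component projection of a cell ensemble
#'
#' Projects cells into a low-dimensional state space by PCA on the
#' centered (optionally unit-variance-scaled) log expression matrix. All
#' cells — across every time point and treatment — should be concatenated
#' into one matrix before fitting, so that coordinates are comparable
#' along the time course. The sign of each component is fixed by making
#' its largest-magnitude gene loading positive, which renders the
#' projection deterministic.
#'
#' @param x an [expression_matrix()].
#' @param K number of components to keep (at most the matrix rank).
#' @param scale logical; scale genes to unit variance before PCA
#'   (default `FALSE`: delta-Cq units are already comparable across
#'   genes).
#' @param genes gene selection; default all genes, controls included.
#' @return an object of class `projection`: list with `scores` (n x K),
#'   `loadings` (m x K, orthonormal columns), `variance_explained`
#'   (fractions of total variance, non-increasing), `center`, `scale`.
#' @export
pca_project <- function(x, K = 3, scale = FALSE, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- .resolve_ids(genes, gene_ids(x))
  v <- x$values[, genes, drop = FALSE]
  if (K > min(dim(v))) stop("K exceeds min(n_cells, n_genes)")
  fit <- stats::prcomp(v, center = TRUE, scale. = scale)
  rank <- sum(fit$sdev > fit$sdev[1L] * 1e-10)
  if (K > rank) stop("K = ", K, " exceeds the matrix rank (", rank, ")")
  scores <- fit$x[, seq_len(K), drop = FALSE]
  loadings <- fit$rotation[, seq_len(K), drop = FALSE]
  for (j in seq_len(K)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = (fit$sdev^2 / sum(fit$sdev^2))[
                   seq_len(K)],
                 center = fit$center,
                 scale = if (isFALSE(fit$scale)) NULL else fit$scale),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("projection: %d cells on %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Quasi-potential landscape over two state-space coordinates
#'
#' Bins cell coordinates on a square lattice spanning the data range
#' padded by 10%, smooths the count surface with a Gaussian filter of
#' width `sigma` (in grid-cell units), and elevates the smoothed density
#' `p` to a quasi-potential `U = -log(p + 1)`. Attractors appear as wells
#' (minima of U at maxima of p); empty regions sit at the base level 0.
#' The filter kernel is renormalized where it is truncated by the grid
#' boundary, so the total smoothed mass equals the number of cells. The
#' landscape is a visual guide to attractor structure, not a dynamical
#' model.
#'
#' @param scores numeric n x 2 matrix of cell coordinates (e.g. the first
#'   two columns of a [pca_project()] score matrix).
#' @param grid_size lattice size per axis (>= 16; default 50).
#' @param sigma Gaussian smoothing width in grid-cell units (default 2).
#' @return an object of class `landscape_grid`: list with `grid` (the
#'   smoothed density p), `elevation` (U), `axes` (bin edges per axis),
#'   `sigma`, `grid_size`.
#' @export
quasipotential <- function(scores, grid_size = 50, sigma = 2) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need two coordinate columns")
  scores <- scores[, 1:2, drop = FALSE]
  if (nrow(scores) < 3L) stop("need at least 3 cells")
  if (sigma <= 0) stop("sigma must be > 0")
  if (grid_size < 16) stop("grid_size must be >= 16")

  edges <- lapply(1:2, function(j) {
    r <- range(scores[, j])
    pad <- 0.1 * diff(r)
    if (pad == 0) pad <- 0.5
    seq(r[1L] - pad, r[2L] + pad, length.out = grid_size + 1L)
  })
  ix <- findInterval(scores[, 1L], edges[[1L]], rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(scores[, 2L], edges[[2L]], rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0, grid_size, grid_size)
  for (i in seq_len(nrow(scores)))
    counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1

  p <- .gauss_smooth_conserve(counts, sigma)
  structure(list(grid = p, elevation = -log(p + 1), axes = edges,
                 sigma = sigma, grid_size = grid_size),
            class = "landscape_grid")
}

# Mass-conserving Gaussian smoothing: each source bin spreads its count
# with a normalized, boundary-truncation-renormalized kernel. Implemented
# as conv(counts / s, K) where s = conv(ones, K) is the in-grid kernel
# mass seen from each source bin.
.gauss_smooth_conserve <- function(counts, sigma) {
  r <- ceiling(4 * sigma)
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2))
  kernel <- outer(k1, k1)
  kernel <- kernel / sum(kernel)
  conv <- function(m) {
    G1 <- nrow(m); G2 <- ncol(m)
    out <- matrix(0, G1, G2)
    for (a in seq_along(off)) {
      da <- off[a]
      si <- max(1, 1 + da):min(G1, G1 + da)      # destination rows
      if (!length(si)) next
      for (b in seq_along(off)) {
        db <- off[b]
        sj <- max(1, 1 + db):min(G2, G2 + db)
        if (!length(sj)) next
        out[si, sj] <- out[si, sj] +
          kernel[a, b] * m[si - da, sj - db, drop = FALSE]
      }
    }
    out
  }
  s <- conv(matrix(1, nrow(counts), ncol(counts)))
  conv(counts / s)
}

#' Local minima of a landscape elevation surface
#'
#' Brute-force scan for strict local minima of the quasi-potential (bins
#' lower than all 8 neighbours), optionally below a depth cutoff.
#'
#' @param landscape a [quasipotential()] result.
#' @param below only report minima with elevation strictly below this
#'   value (default 0, i.e. any occupied well).
#' @return data.frame with bin indices `i`, `j`, bin-center coordinates
#'   `x`, `y` and `elevation`.
#' @export
landscape_minima <- function(landscape, below = 0) {
  stopifnot(inherits(landscape, "landscape_grid"))
  u <- landscape$elevation
  G <- nrow(u)
  hits <- list()
  for (i in 2:(G - 1L)) for (j in 2:(G - 1L)) {
    nb <- u[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
    if (u[i, j] < below && sum(u[i, j] < nb) == 8L)
      hits[[length(hits) + 1L]] <- data.frame(i = i, j = j, elevation = u[i, j])
  }
  if (!length(hits))
    return(data.frame(i = integer(), j = integer(), x = numeric(),
                      y = numeric(), elevation = numeric()))
  out <- do.call(rbind, hits)
  mid <- function(e, idx) (e[idx] + e[idx + 1L]) / 2
  out$x <- mid(landscape$axes[[1L]], out$i)
  out$y <- mid(landscape$axes[[2L]], out$j)
  out[c("i", "j", "x", "y", "elevation")]
}
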