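# Shared fixtures and independent oracles for the test suite.

# ExpressionMatrix from a bare matrix, auto-naming cells/genes.
make_em <- function(values, gene_roles = NULL, cell_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%02d", seq_len(ncol(values)))
  expression_matrix(values, gene_roles = gene_roles, cell_meta = cell_meta)
}

# Brute-force Pearson correlation from raw moments (the textbook formula),
# independent of stats::cor.
pearson_oracle <- function(u, v) {
  n <- length(u)
  num <- sum(u * v) - sum(u) * sum(v) / n
  den <- sqrt((sum(u^2) - sum(u)^2 / n) * (sum(v^2) - sum(v)^2 / n))
  num / den
}

# Full pairwise oracle over the columns of m (NA for zero-variance).
pearson_matrix_oracle <- function(m) {
  p <- ncol(m)
  out <- matrix(NA_real_, p, p)
  sds <- apply(m, 2, stats::sd)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (sds[i] > 0 && sds[j] > 0)
      out[i, j] <- if (i == j) 1 else pearson_oracle(m[, i], m[, j])
  }
  out
}

# The 6 cells x 4 genes toy matrix used for hand-verifiable I_C checks.
toy_matrix_6x4 <- function() {
  make_em(matrix(c(1, 2, 3, 2,
                   2, 3, 4, 4,
                   1, 1, 3, 2,
                   3, 4, 5, 5,
                   2, 2, 4, 3,
                   1, 3, 3, 3), nrow = 6, byrow = TRUE))
}

# Rank-1 strictly positive matrix: every cell pair and gene pair is
# perfectly collinear with positive slope.
rank1_em <- function(n = 12, m = 5) {
  make_em(outer(seq(1, 2, length.out = n), seq(1, 3, length.out = m)))
}

# Memoized benchmark scenario runs (they cost seconds each).
.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(seed = 1, n_cells = 500) {
  key <- paste0("s", seed, "_", n_cells)
  if (is.null(.scenario_cache[[key]]))
    .scenario_cache[[key]] <- default_scenario(seed = seed,
                                               n_cells = n_cells)
  .scenario_cache[[key]]
}

# Write a small Cq fixture (records + LOD) to dir; returns the two paths.
# Two cells x two target genes + one control, triplicates, one all-fail
# gene for cell c2.
write_cq_fixture <- function(dir, sep = ",") {
  rec <- data.frame(
    cell = rep(c("c1", "c2"), each = 9),
    gene = rep(rep(c("CTRL", "GA", "GB"), each = 3), 2),
    replicate = rep(1:3, 6),
    cq = c(20.0, 20.2, 19.8, 25.0, 25.2, 26.0, 27.0, 27.4, 27.2,
           20.1, 19.9, 20.0, 24.5, 24.7, 24.6, 31.0, 32.0, 31.5))
  lod <- data.frame(gene = c("CTRL", "GA", "GB"), lod = c(32, 30, 30))
  cq_path <- file.path(dir, "cq.csv")
  lod_path <- file.path(dir, "lod.csv")
  utils::write.table(rec, cq_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(lod, lod_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  list(cq = cq_path, lod = lod_path)
}
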