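test_that("I_C identities: rank-1 unity, duplication and relabeling invariance", {
  expect_equal(compute_ic(rank1_em(), B_sem = 0)$ic, 1)

  # duplication is exactly invariant on a collinear ensemble (all R = 1)
  r1 <- rank1_em(n = 8, m = 5)
  dup1 <- rbind(r1$values, r1$values)
  rownames(dup1) <- sprintf("c%02d", 1:16)
  expect_equal(compute_ic(expression_matrix(dup1), B_sem = 0)$ic, 1)

  # on a general ensemble, duplicating every cell leaves every gene-gene
  # correlation unchanged and mixes unit self-pairs into the cell-cell
  # mean by exact pair counting: m' = (2 m (n-1) + 1) / (2n - 1)
  x <- toy_matrix_6x4()
  s <- correlation_summary(x)
  n <- s$n_cells
  dup <- rbind(x$values, x$values)
  rownames(dup) <- sprintf("c%02d", 1:(2 * n))
  sd2 <- correlation_summary(expression_matrix(dup))
  expect_equal(sd2$mean_abs_gene_gene, s$mean_abs_gene_gene,
               tolerance = 1e-12)
  expect_equal(sd2$mean_cell_cell,
               (2 * s$mean_cell_cell * (n - 1) + 1) / (2 * n - 1),
               tolerance = 1e-12)

  set.seed(21)
  v <- toy_matrix_6x4()$values
  perm <- v[sample(6), sample(4)]
  expect_equal(compute_ic(expression_matrix(perm), B_sem = 0)$ic,
               compute_ic(x, B_sem = 0)$ic, tolerance = 1e-12)
})

test_that("I_C matches the brute-force pairwise-Pearson oracle on the toy matrix", {
  # frozen from the moment oracle: mean|R(g_i,g_j)| / mean R(S^k,S^l)
  res <- compute_ic(toy_matrix_6x4(), B_sem = 0)
  expect_equal(res$ic, 1.040717269782758, tolerance = 1e-12)
  v <- toy_matrix_6x4()$values
  cc <- pearson_matrix_oracle(t(v))
  gg <- pearson_matrix_oracle(v)
  oracle <- mean(abs(gg[upper.tri(gg)])) / mean(cc[upper.tri(cc)])
  expect_equal(res$ic, oracle, tolerance = 1e-12)
})

test_that("a non-positive cell-cell mean is rejected as meaningless", {
  set.seed(4)
  half <- matrix(rnorm(50), 10, 5)
  v <- rbind(half, -half) + rnorm(100, sd = 0.01)
  rownames(v) <- sprintf("c%02d", 1:20); colnames(v) <- paste0("g", 1:5)
  expect_error(compute_ic(expression_matrix(v), B_sem = 0),
               "denominator non-positive")
})

test_that("the cell bootstrap yields a reproducible, positive SEM", {
  set.seed(31)
  # shared gene-mean profile keeps the cell-cell mean positive
  v <- outer(rep(1, 20), seq(-2, 2, length.out = 10)) +
    matrix(rnorm(200, sd = 0.5), 20, 10)
  dimnames(v) <- list(sprintf("c%02d", 1:20), paste0("g", 1:10))
  x <- expression_matrix(v)
  r1 <- compute_ic(x, B_sem = 50, seed = 99)
  r2 <- compute_ic(x, B_sem = 50, seed = 99)
  expect_identical(r1$sem, r2$sem)
  expect_gt(r1$sem, 0)
})

test_that("time courses group by metadata, skip small groups audibly", {
  set.seed(41)
  v <- outer(rep(1, 25), seq(-2, 2, length.out = 6)) +
    matrix(rnorm(25 * 6, sd = 0.4), 25, 6)
  dimnames(v) <- list(sprintf("c%02d", 1:25), paste0("g", 1:6))
  meta <- data.frame(cell_id = rownames(v),
                     time_point = rep(c("d0", "d1", "d3"), c(10, 10, 5)))
  x <- expression_matrix(v, cell_meta = meta)
  expect_message(tc <- ic_timecourse(x, B_sem = 0), "skipped.*5 cells")
  expect_equal(tc$time_point, c("d0", "d1"))

  # two cell-wise identical groups give identical I_C
  v2 <- rbind(v[1:10, ], v[1:10, ])
  rownames(v2) <- sprintf("c%02d", 1:20)
  meta2 <- data.frame(cell_id = rownames(v2),
                      time_point = rep(c("d0", "d1"), each = 10))
  tc2 <- ic_timecourse(expression_matrix(v2, cell_meta = meta2), B_sem = 0)
  expect_equal(tc2$ic[1], tc2$ic[2])
})

test_that("I_C peaks near the tipping point of a simulated time course", {
  tc <- ic_timecourse(as_expression_matrix(cached_scenario(1)), B_sem = 0)
  expect_equal(tc$time_point, c("t0", "t1", "t2", "t3"))
  expect_gt(tc$ic[3], tc$ic[1])            # near > far from bifurcation
  expect_equal(which.max(tc$ic), 3L)
})

test_that("permutation null is valid, seeded, and saturates on structure", {
  expect_error(permutation_null(rank1_em(), B = 50), "at least 99")

  set.seed(51)
  v <- outer(rep(1, 30), seq(-2, 2, length.out = 8)) +
    matrix(rnorm(30 * 8, sd = 0.5), 30, 8)
  dimnames(v) <- list(sprintf("c%02d", 1:30), paste0("g", 1:8))
  x <- expression_matrix(v)
  n1 <- permutation_null(x, B = 99, seed = 5)
  n2 <- permutation_null(x, B = 99, seed = 5)
  expect_identical(n1$p_value, n2$p_value)
  expect_true(n1$p_value > 0 && n1$p_value <= 1)
  expect_equal(length(n1$null_values), 99L)

  # perfect rank-1 structure: no permutation can match it
  r1 <- rank1_em(n = 30, m = 8)
  jitter <- matrix(rnorm(240, sd = 1e-6), 30, 8)   # break exact ties
  xs <- expression_matrix(r1$values + jitter)
  ns <- permutation_null(xs, B = 99, seed = 6)
  expect_equal(ns$p_value, 1 / 100)
})

test_that("gene subsampling: full panel is exact, spread shrinks with size", {
  set.seed(61)
  x <- as_expression_matrix(cached_scenario(1))
  t2 <- subset_cells(x, cells = grepl("^t2_", cell_ids(x)))
  full <- compute_ic(t2, B_sem = 0)$ic
  tab <- gene_subsample_robustness(t2, sizes = 12, n_draws = 5, seed = 1)
  expect_equal(tab$ic, rep(full, 5), tolerance = 1e-12)
  expect_equal(attr(tab, "summary")$sd_ic, 0)

  expect_error(gene_subsample_robustness(t2, sizes = 5, n_draws = 0),
               "n_draws")
  expect_error(gene_subsample_robustness(t2, sizes = 40, n_draws = 1),
               "exceeds")
  expect_warning(gene_subsample_robustness(t2, sizes = c(2, 5),
                                           n_draws = 2, seed = 1),
                 "below 3")
})
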