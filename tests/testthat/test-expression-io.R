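test_that("Cq tables parse from delimited text with tolerant headers", {
  dir <- withr::local_tempdir()
  paths <- write_cq_fixture(dir)
  tab <- read_cq_table(paths$cq, paths$lod, control_genes = "CTRL")
  expect_s3_class(tab, "CqTable")
  expect_equal(nrow(tab$records), 18L)
  expect_equal(sort(unique(tab$records$gene)), c("CTRL", "GA", "GB"))

  # tab-delimited variant, auto-detected
  paths_tsv <- write_cq_fixture(withr::local_tempdir(), sep = "\t")
  tab2 <- read_cq_table(paths_tsv$cq, paths_tsv$lod)
  expect_equal(tab2$records, tab$records)

  # case-insensitive header match
  raw <- read.csv(paths$cq)
  names(raw) <- c("Cell", "GENE", "Replicate", "Cq")
  path3 <- file.path(dir, "cq_case.csv")
  write.csv(raw, path3, row.names = FALSE, quote = FALSE)
  tab3 <- read_cq_table(path3, paths$lod)
  expect_equal(tab3$records$cq, tab$records$cq)

  # missing required column is a format error naming the column
  path4 <- file.path(dir, "cq_nogene.csv")
  write.csv(raw[-2], path4, row.names = FALSE, quote = FALSE)
  expect_error(read_cq_table(path4, paths$lod), "gene")

  # gene without an LOD entry fails validation; extra LOD genes warn
  lod_small <- data.frame(gene = c("CTRL", "GA"), lod = c(32, 30))
  path5 <- file.path(dir, "lod_small.csv")
  write.csv(lod_small, path5, row.names = FALSE, quote = FALSE)
  expect_error(read_cq_table(paths$cq, path5), "GB")
  lod_extra <- data.frame(gene = c("CTRL", "GA", "GB", "GX"),
                          lod = c(32, 30, 30, 28))
  path6 <- file.path(dir, "lod_extra.csv")
  write.csv(lod_extra, path6, row.names = FALSE, quote = FALSE)
  expect_warning(read_cq_table(paths$cq, path6), "GX")
})

test_that("replicate collapsing filters by LOD then takes the median", {
  rec <- data.frame(cell = "c1", gene = rep(c("A", "B", "C"), c(3, 2, 2)),
                    replicate = c(1:3, 1:2, 1:2),
                    cq = c(25.0, 25.2, 26.0, 25.0, 31.0, 31.0, 32.0))
  tab <- cq_table(rec, lod = c(A = 30, B = 30, C = 30))
  col <- collapse_replicates(tab)
  got <- setNames(col$records$cq, col$records$gene)
  expect_identical(got[["A"]], 25.2)       # median of three passing
  expect_identical(got[["B"]], 25.0)       # median over single passing rep
  expect_true(is.na(got[["C"]]))           # all replicates fail the cutoff

  # idempotence: collapsing a collapsed table changes nothing
  expect_identical(collapse_replicates(col)$records, col$records)
})

test_that("delta-Cq normalization references controls and floors non-detects", {
  rec <- data.frame(
    cell = rep(c("c1", "c2", "c3"), each = 4),
    gene = rep(c("CTRL1", "CTRL2", "GA", "GB"), 3),
    replicate = 1L,
    cq = c(19, 21, 25, 28,       # c1: ref 20, both targets detected
           20, 20, 24, NA,       # c2: GB non-detect
           20, 20, NA, NA))      # c3: no target detected -> dropped
  tab <- cq_table(rec, lod = c(CTRL1 = 32, CTRL2 = 32, GA = 30, GB = 30),
                  control_genes = c("CTRL1", "CTRL2"))
  expect_message(x <- normalize_delta_cq(tab, floor_margin = 1),
                 "no target gene")
  expect_equal(sort(cell_ids(x)), c("c1", "c2"))
  expect_equal(x$values["c1", "GA"], -5)           # 20 - 25
  expect_equal(x$values["c2", "GB"], -11)          # 20 - (30 + 1)
  expect_false(x$detect_mask["c2", "GB"])
  expect_true(all(x$detect_mask[, "GA"]))
  expect_equal(unname(x$gene_roles[c("CTRL1", "GA")]),
               c("control", "target"))

  # imputed entries sit strictly below detected entries of the same gene
  expect_true(x$values["c2", "GB"] < min(x$values[x$detect_mask[, "GB"], "GB"]))

  # a cell with no detected control gene is dropped with a message
  rec2 <- rbind(rec[1:8, ],
                data.frame(cell = "c4", gene = c("CTRL1", "CTRL2", "GA", "GB"),
                           replicate = 1L, cq = c(NA, NA, 24, 25)))
  tab2 <- cq_table(rec2, lod = c(CTRL1 = 32, CTRL2 = 32, GA = 30, GB = 30),
                   control_genes = c("CTRL1", "CTRL2"))
  expect_message(x2 <- normalize_delta_cq(tab2), "no detected control")
  expect_false("c4" %in% cell_ids(x2))
})

test_that("ExpressionMatrix round-trips through delimited text exactly", {
  set.seed(42)
  v <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("c", 1:5), paste0("g", 1:4)))
  meta <- data.frame(cell_id = paste0("c", 1:5),
                     time_point = rep(c("d0", "d3"), c(2, 3)),
                     treatment = "EPO", fraction = "M")
  mask <- matrix(TRUE, 5, 4); mask[2, 3] <- FALSE
  x <- expression_matrix(v, cell_meta = meta,
                         gene_roles = c(g4 = "control"),
                         detect_mask = mask)
  path <- file.path(withr::local_tempdir(), "em.csv")
  write_expression_matrix(x, path)
  y <- read_expression_matrix(path)
  expect_identical(y$values, x$values)
  expect_identical(y$cell_meta, x$cell_meta)
  expect_identical(y$gene_roles, x$gene_roles)
  expect_identical(y$detect_mask, x$detect_mask)
})

test_that("ExpressionMatrix validation rejects malformed input", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("c1", "c2"), c("g1", "g1")))
  expect_error(expression_matrix(v), "duplicate gene_ids")

  v2 <- matrix(1:4, 2, 2, dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_error(expression_matrix(v2, cell_meta = data.frame(
    cell_id = c("c1", "cX"), time_point = "d0")), "cX")
  expect_error(expression_matrix(v2, cell_meta = data.frame(
    cell_id = "c1", time_point = "d0")), "c2")
})
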