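#' Construct a single-cell qPCR Cq table
#'
#' Raw quantification cycles per (cell, gene, technical replicate), with
#' per-assay limit-of-detection (LOD) cutoffs. A lower Cq means more
#' transcript; a Cq at or beyond the assay's LOD is treated as a
#' non-detect during replicate collapsing.
#'
#' @param records data.frame with columns `cell`, `gene`, `replicate`
#'   (integer >= 1) and `cq` (cycles; `NA` = non-detect).
#' @param lod named numeric vector mapping gene id to its LOD cutoff Cq.
#'   Every gene appearing in `records` must have an entry.
#' @param control_genes character vector of housekeeping gene ids used as
#'   the delta-Cq reference.
#' @return an object of class `CqTable`.
#' @export
cq_table <- function(records, lod, control_genes = character()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("cell", "gene", "replicate", "cq")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  records <- records[needed]
  records$cell <- as.character(records$cell)
  records$gene <- as.character(records$gene)
  records$replicate <- as.integer(records$replicate)
  records$cq <- as.numeric(records$cq)
  if (any(records$replicate < 1L, na.rm = TRUE))
    stop("replicate indices must be >= 1")
  bad <- !is.na(records$cq) & (!is.finite(records$cq) | records$cq <= 0)
  if (any(bad))
    stop("Cq values must be finite and > 0 (use NA for non-detects)")
  if (is.null(names(lod)) || !is.numeric(lod))
    stop("'lod' must be a named numeric vector (gene -> cutoff Cq)")
  absent <- setdiff(unique(records$gene), names(lod))
  if (length(absent))
    stop("gene(s) without an LOD entry: ", paste(absent, collapse = ", "))
  extra <- setdiff(names(lod), unique(records$gene))
  if (length(extra))
    warning("LOD entries for gene(s) not in records ignored: ",
            paste(extra, collapse = ", "))
  structure(list(records = records,
                 lod = lod[intersect(names(lod), unique(records$gene))],
                 control_genes = as.character(control_genes)),
            class = "CqTable")
}

#' @export
print.CqTable <- function(x, ...) {
  cat(sprintf("CqTable: %d records, %d cells, %d genes (%d control)\n",
              nrow(x$records), length(unique(x$records$cell)),
              length(unique(x$records$gene)), length(x$control_genes)))
  cat(sprintf("  non-detects: %d\n", sum(is.na(x$records$cq))))
  invisible(x)
}

# Read one header line and pick the delimiter: tab if the header contains a
# tab, else comma. Spreadsheet exports ship as either.
.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA"), comment.char = "",
                    quote = "\"")
}

# Case-insensitive header lookup; errors name the missing column.
.require_column <- function(df, name, path) {
  hit <- which(tolower(names(df)) == tolower(name))
  if (!length(hit))
    stop(sprintf("'%s' lacks required column '%s'", path, name))
  df[[hit[1L]]]
}

#' Read a raw Cq table and its LOD map from delimited text
#'
#' The Cq file needs columns `cell`, `gene`, `replicate`, `cq`
#' (case-insensitive; an empty `cq` field is a non-detect). The LOD file
#' needs columns `gene` and `lod`. Comma- or tab-delimited is detected
#' from the header line. Genes listed in the LOD file but absent from the
#' records are ignored with a warning; a recorded gene missing from the
#' LOD map is an error.
#'
#' @param path path to the Cq records file.
#' @param lod_path path to the gene -> LOD cutoff file.
#' @param control_genes character vector of housekeeping gene ids.
#' @return a validated [cq_table()].
#' @export
read_cq_table <- function(path, lod_path, control_genes = character()) {
  raw <- .read_delim(path)
  records <- data.frame(
    cell = as.character(.require_column(raw, "cell", path)),
    gene = as.character(.require_column(raw, "gene", path)),
    replicate = as.integer(.require_column(raw, "replicate", path)),
    cq = as.numeric(.require_column(raw, "cq", path)),
    stringsAsFactors = FALSE)
  lraw <- .read_delim(lod_path)
  lod <- as.numeric(.require_column(lraw, "lod", lod_path))
  names(lod) <- as.character(.require_column(lraw, "gene", lod_path))
  cq_table(records, lod, control_genes = control_genes)
}

#' Collapse technical replicates to one Cq per (cell, gene)
#'
#' Replicates failing the assay's LOD cutoff (Cq at or above the cutoff,
#' or non-detect) are discarded first; the collapsed value is the median
#' of the surviving replicates. If no replicate passes, the collapsed
#' value is a non-detect. Idempotent: collapsing a collapsed table is a
#' no-op.
#'
#' @param cq a `CqTable`.
#' @return a `CqTable` with one record per (cell, gene), replicate index 1.
#' @export
collapse_replicates <- function(cq) {
  stopifnot(inherits(cq, "CqTable"))
  rec <- cq$records
  cutoff <- cq$lod[rec$gene]
  ok <- !is.na(rec$cq) & rec$cq < cutoff
  key <- paste(rec$cell, rec$gene, sep = "\r")
  med <- vapply(split(rec$cq[ok], key[ok]), stats::median, numeric(1))
  keys <- unique(key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    cell = vapply(parts, `[`, character(1), 1L),
    gene = vapply(parts, `[`, character(1), 2L),
    replicate = 1L,
    cq = unname(med[keys]),
    stringsAsFactors = FALSE)
  cq_table(out, cq$lod, control_genes = cq$control_genes)
}

#' Delta-Cq normalization to a log2 expression matrix
#'
#' Per cell, the reference level is the mean collapsed Cq of that cell's
#' detected control genes; log2 expression of a gene is
#' `reference - Cq`, so one PCR cycle is one log2 unit and a higher value
#' means more transcript. Non-detects are imputed at the expression floor
#' `reference - (LOD + floor_margin)`, just below the least detectable
#' level, and flagged `FALSE` in the detection mask. Cells detecting no
#' control gene, or no target gene at all, are dropped with a message.
#'
#' @param cq a replicate-collapsed `CqTable` with non-empty
#'   `control_genes`.
#' @param floor_margin cycles below the LOD at which non-detects are
#'   imputed (default 1).
#' @param cell_meta optional per-cell metadata passed through to
#'   [expression_matrix()].
#' @return an [expression_matrix()] over all genes (targets and controls).
#' @export
normalize_delta_cq <- function(cq, floor_margin = 1, cell_meta = NULL) {
  stopifnot(inherits(cq, "CqTable"))
  if (!length(cq$control_genes))
    stop("delta-Cq normalization needs at least one control gene")
  rec <- cq$records
  if (anyDuplicated(paste(rec$cell, rec$gene)))
    stop("table not replicate-collapsed: run collapse_replicates() first")

  genes <- sort(unique(rec$gene))
  controls <- intersect(cq$control_genes, genes)
  if (!length(controls))
    stop("none of the control genes appear in the records")
  targets <- setdiff(genes, controls)
  cells <- unique(rec$cell)

  wide <- matrix(NA_real_, length(cells), length(genes),
                 dimnames = list(cells, genes))
  wide[cbind(match(rec$cell, cells), match(rec$gene, genes))] <- rec$cq

  ctrl <- wide[, controls, drop = FALSE]
  ref <- rowMeans(ctrl, na.rm = TRUE)
  no_ctrl <- !is.finite(ref)
  if (any(no_ctrl))
    message(sum(no_ctrl), " cell(s) dropped: no detected control gene (",
            paste(cells[no_ctrl], collapse = ", "), ")")
  no_target <- rowSums(!is.na(wide[, targets, drop = FALSE])) == 0L
  if (any(no_target & !no_ctrl))
    message(sum(no_target & !no_ctrl),
            " cell(s) dropped: no target gene detected")
  keep <- !no_ctrl & !no_target
  if (sum(keep) < 2L)
    stop("fewer than 2 cells survive preprocessing")

  wide <- wide[keep, , drop = FALSE]
  ref <- ref[keep]
  detect <- !is.na(wide)
  expr <- ref - wide                        # detected entries
  floor_cq <- matrix(cq$lod[genes] + floor_margin, nrow(wide), length(genes),
                     byrow = TRUE)
  expr[!detect] <- (ref - floor_cq)[!detect]

  roles <- ifelse(genes %in% controls, "control", "target")
  names(roles) <- genes
  expression_matrix(expr, cell_meta = cell_meta, gene_roles = roles,
                    detect_mask = detect)
}

#' Write / read an ExpressionMatrix as delimited text
#'
#' `write_expression_matrix()` writes the value matrix (cells as rows,
#' first column `cell_id`) plus three sidecar tables derived from `path`:
#' `<stem>_cells.csv` (cell metadata), `<stem>_genes.csv` (gene roles) and
#' `<stem>_detected.csv` (detection mask). `read_expression_matrix()`
#' reverses this; the round trip reproduces values to full precision and
#' all metadata.
#'
#' @param x an `ExpressionMatrix`.
#' @param path path of the value matrix file (`.csv`).
#' @param meta_path,genes_path,mask_path sidecar paths; by default derived
#'   from `path`.
#' @return `write_expression_matrix()` returns `path` invisibly;
#'   `read_expression_matrix()` returns an `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(x, path,
                                    meta_path = .sidecar(path, "cells"),
                                    genes_path = .sidecar(path, "genes"),
                                    mask_path = .sidecar(path, "detected")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  .write_matrix_csv(x$values, path, digits = 17)
  utils::write.csv(x$cell_meta, meta_path, row.names = FALSE)
  utils::write.csv(data.frame(gene_id = names(x$gene_roles),
                              role = unname(x$gene_roles)),
                   genes_path, row.names = FALSE)
  .write_matrix_csv(x$detect_mask * 1L, mask_path, digits = NULL)
  invisible(path)
}

.sidecar <- function(path, tag) {
  stem <- sub("\\.[^./\\\\]+$", "", path)
  ext <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", stem)), "", path)
  if (!nzchar(ext)) ext <- ".csv"
  paste0(stem, "_", tag, ext)
}

.write_matrix_csv <- function(m, path, digits = 17) {
  df <- as.data.frame(m, check.names = FALSE)
  if (!is.null(digits))
    df[] <- lapply(df, function(v) formatC(v, digits = digits, format = "g"))
  df <- cbind(cell_id = rownames(m), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.read_matrix_csv <- function(path) {
  df <- .read_delim(path)
  if (!"cell_id" %in% names(df)) stop("'", path, "' lacks a cell_id column")
  m <- as.matrix(df[setdiff(names(df), "cell_id")])
  rownames(m) <- as.character(df$cell_id)
  storage.mode(m) <- "double"
  m
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path,
                                   meta_path = .sidecar(path, "cells"),
                                   genes_path = .sidecar(path, "genes"),
                                   mask_path = .sidecar(path, "detected")) {
  values <- .read_matrix_csv(path)
  meta <- NULL
  if (file.exists(meta_path)) meta <- .read_delim(meta_path)
  roles <- NULL
  if (file.exists(genes_path)) {
    g <- .read_delim(genes_path)
    roles <- stats::setNames(as.character(g$role), as.character(g$gene_id))
  }
  mask <- NULL
  if (file.exists(mask_path)) {
    mask <- .read_matrix_csv(mask_path)
    mask <- mask[rownames(values), colnames(values), drop = FALSE] > 0
  }
  expression_matrix(values, cell_meta = meta, gene_roles = roles,
                    detect_mask = mask)
}
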