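#' Construct an ExpressionMatrix
#'
#' The canonical container of this package: an `n` cells x `m` genes matrix
#' of log2-scale expression values (higher value = more transcript), with
#' per-cell metadata, per-gene role labels and a detection mask marking
#' entries that were imputed at the expression floor rather than measured.
#'
#' @param values numeric matrix, cells as rows and genes as columns; must
#'   carry unique row (cell) and column (gene) names.
#' @param cell_meta data.frame with one row per cell and columns
#'   `time_point`, `treatment`, `fraction` (any subset; missing columns are
#'   filled with `NA`). Rows are matched to cells either by a `cell_id`
#'   column or by row names.
#' @param gene_roles character vector of `"target"` / `"control"` labels,
#'   named by gene or in column order; default all `"target"`. Control
#'   genes are the housekeeping references of the assay and are excluded
#'   from correlation analyses by default.
#' @param detect_mask logical matrix of the same shape as `values`; `FALSE`
#'   marks a floor-imputed non-detect. Default all `TRUE`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `cell_meta`, `gene_roles`, `detect_mask`.
#' @export
expression_matrix <- function(values, cell_meta = NULL, gene_roles = NULL,
                              detect_mask = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have cell (row) and gene (column) names")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 cells and 2 genes")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell_ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene_ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite with no missing entries ",
         "(impute non-detects before construction)")

  cell_ids <- rownames(values)
  gene_ids <- colnames(values)

  meta <- data.frame(cell_id = cell_ids,
                     time_point = NA_character_,
                     treatment = NA_character_,
                     fraction = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
    key <- if ("cell_id" %in% names(cell_meta)) as.character(cell_meta$cell_id)
           else rownames(cell_meta)
    orphans <- setdiff(key, cell_ids)
    if (length(orphans))
      stop("metadata rows do not match any cell: ",
           paste(orphans, collapse = ", "))
    missing <- setdiff(cell_ids, key)
    if (length(missing))
      stop("metadata missing for cell(s): ", paste(missing, collapse = ", "))
    idx <- match(cell_ids, key)
    for (col in intersect(c("time_point", "treatment", "fraction"),
                          names(cell_meta)))
      meta[[col]] <- as.character(cell_meta[[col]][idx])
  }
  rownames(meta) <- cell_ids

  roles <- rep("target", length(gene_ids))
  names(roles) <- gene_ids
  if (!is.null(gene_roles)) {
    gene_roles <- unlist(gene_roles)
    if (!is.null(names(gene_roles))) {
      unknown <- setdiff(names(gene_roles), gene_ids)
      if (length(unknown))
        stop("gene_roles name unknown gene(s): ",
             paste(unknown, collapse = ", "))
      roles[names(gene_roles)] <- as.character(gene_roles)
    } else {
      if (length(gene_roles) != length(gene_ids))
        stop("unnamed gene_roles must have one entry per gene")
      roles[] <- as.character(gene_roles)
    }
    if (!all(roles %in% c("target", "control")))
      stop("gene roles must be 'target' or 'control'")
  }

  if (is.null(detect_mask)) {
    detect_mask <- matrix(TRUE, nrow(values), ncol(values),
                          dimnames = dimnames(values))
  } else {
    detect_mask <- as.matrix(detect_mask)
    if (!identical(dim(detect_mask), dim(values)))
      stop("detect_mask shape must match values")
    dimnames(detect_mask) <- dimnames(values)
    storage.mode(detect_mask) <- "logical"
  }

  structure(list(values = values, cell_meta = meta, gene_roles = roles,
                 detect_mask = detect_mask),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$gene_roles == "control")))
  n_imp <- sum(!x$detect_mask)
  cat(sprintf("  imputed non-detects: %d (%.1f%%)\n", n_imp,
              100 * n_imp / length(x$values)))
  grp <- unique(x$cell_meta$time_point)
  if (!all(is.na(grp)))
    cat("  time points:", paste(grp, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Cell and gene identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of identifiers.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' Names of target (non-control) genes
#' @param x an `ExpressionMatrix`.
#' @return character vector of gene ids with role `"target"`.
#' @export
target_genes <- function(x) names(x$gene_roles)[x$gene_roles == "target"]

# Resolve a cell or gene selection (names, logical or integer index) to
# names; NULL means the provided default.
.resolve_ids <- function(sel, universe, default = universe) {
  if (is.null(sel)) return(default)
  if (is.logical(sel)) {
    if (length(sel) != length(universe))
      stop("logical selection has wrong length")
    return(universe[sel])
  }
  if (is.numeric(sel)) return(universe[sel])
  unknown <- setdiff(sel, universe)
  if (length(unknown))
    stop("unknown identifier(s): ", paste(unknown, collapse = ", "))
  as.character(sel)
}

#' Subset an ExpressionMatrix by cells and/or genes
#'
#' @param x an `ExpressionMatrix`.
#' @param cells,genes selections (names, logical or integer indices);
#'   `NULL` keeps everything.
#' @return an `ExpressionMatrix` restricted to the selection.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  cells <- .resolve_ids(cells, cell_ids(x))
  genes <- .resolve_ids(genes, gene_ids(x))
  expression_matrix(x$values[cells, genes, drop = FALSE],
                    cell_meta = x$cell_meta[cells, , drop = FALSE],
                    gene_roles = x$gene_roles[genes],
                    detect_mask = x$detect_mask[cells, genes, drop = FALSE])
}
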