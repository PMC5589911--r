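# Matrix-backed expression container with rpkm/tpm layers.

#' Build an expression matrix object
#'
#' Container for a genes x cells read-count matrix together with gene
#' annotation, cell metadata and per-cell library sizes. rpkm and tpm layers
#' are filled by [compute_rpkm()] / [compute_tpm()].
#'
#' `library_size` is the per-cell total of uniquely aligned reads counted to
#' genes. By default it is the column sum of `counts` (all counted reads are
#' genic); a larger externally measured total may be supplied, never a
#' smaller one.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), cells
#'   in columns (colnames = cell ids).
#' @param genes Gene annotation tibble covering at least the matrix genes.
#' @param cells Cell metadata tibble covering the matrix cells.
#' @param library_size Optional named per-cell totals; defaults to column sums.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(counts, genes, cells, library_size = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) abort("negative counts")
  genes <- validate_gene_annotation(genes)
  cells <- validate_cell_meta(cells)
  miss_g <- setdiff(rownames(counts), genes$gene_id)
  if (length(miss_g) > 0) {
    abort(paste0("genes present in matrix but missing from annotation: ",
                 paste(head(miss_g, 10), collapse = ", ")))
  }
  miss_c <- setdiff(colnames(counts), cells$cell_id)
  if (length(miss_c) > 0) {
    abort(paste0("cells present in matrix but missing from metadata: ",
                 paste(head(miss_c, 10), collapse = ", ")))
  }
  csum <- colSums(counts)
  if (is.null(library_size)) {
    library_size <- csum
  } else {
    library_size <- library_size[colnames(counts)]
    if (any(is.na(library_size))) abort("library_size missing for some cells")
    if (any(library_size < csum - 1e-8)) {
      abort("library_size smaller than the genic column sum for some cell(s)")
    }
  }
  structure(
    list(
      counts = counts,
      genes = genes[match(rownames(counts), genes$gene_id), , drop = FALSE],
      cells = cells[match(colnames(counts), cells$cell_id), , drop = FALSE],
      library_size = setNames(as.numeric(library_size), colnames(counts)),
      layers = list()
    ),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells; layers: ",
      if (length(x$layers)) paste(names(x$layers), collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Tidy an expression matrix into a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return Long tibble with `gene_id`, `cell_id`, `counts` and one column per
#'   filled layer.
#' @export
tidy.expr_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame.table(x$counts, responseName = "counts",
                                       stringsAsFactors = FALSE)) |>
    rename(gene_id = "Var1", cell_id = "Var2")
  for (nm in names(x$layers)) {
    out[[nm]] <- as.vector(x$layers[[nm]])
  }
  out
}

#' Write an expression layer as a TSV matrix
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @param layer `"counts"` or a filled layer name (`"rpkm"`, `"tpm"`).
#' @export
write_expr_layer <- function(x, path, layer = "counts") {
  m <- if (layer == "counts") x$counts else x$layers[[layer]]
  if (is.null(m)) abort(paste0("layer not filled: ", layer))
  df <- as_tibble(m, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a counts TSV matrix back into an expr_matrix
#'
#' @param path Counts TSV (gene_id column + one column per cell).
#' @param genes,cells Annotation and metadata tibbles.
#' @param library_size Optional per-cell totals.
#' @return An `expr_matrix`.
#' @export
read_expr_counts <- function(path, genes, cells, library_size = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expr_matrix(m, genes, cells, library_size)
}
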