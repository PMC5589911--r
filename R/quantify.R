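# rpkm / tpm layers and the expressed-gene mask.

#' Fill the rpkm layer
#'
#' rpkm(g, c) = counts(g, c) * 1e9 / (exonic_length(g) * library_size(c)).
#' The length term is the gene's exonic length (counting is exonic), not its
#' genomic span. Cells with library size 0 get an all-zero column.
#'
#' @param x An [expr_matrix()].
#' @param library Which per-cell total to use as the denominator:
#'   `"genic"` recomputes column sums of the counts (default), `"stored"`
#'   uses the library sizes supplied at construction (e.g. all uniquely
#'   aligned reads).
#' @return `x` with `layers$rpkm` filled.
#' @export
compute_rpkm <- function(x, library = c("genic", "stored")) {
  library <- match.arg(library)
  lib <- if (library == "genic") colSums(x$counts) else x$library_size
  len <- x$genes$exonic_length
  if (any(is.na(len)) || any(len <= 0)) {
    abort(paste0("missing/invalid exonic_length for gene(s): ",
                 paste(head(x$genes$gene_id[is.na(len) | len <= 0], 10), collapse = ", ")))
  }
  denom <- outer(len, lib)
  rpkm <- ifelse(denom > 0, x$counts * 1e9 / denom, 0)
  dimnames(rpkm) <- dimnames(x$counts)
  x$layers$rpkm <- rpkm
  x
}

#' Fill the tpm layer
#'
#' tpm(g, c) = rate(g, c) * 1e6 / sum_g rate(g, c), with
#' rate = counts / exonic_length. Column sums are 1e6 for any cell with
#' nonzero counts; all-zero cells yield an all-zero column with a warning.
#'
#' @param x An [expr_matrix()].
#' @return `x` with `layers$tpm` filled.
#' @export
compute_tpm <- function(x) {
  rate <- x$counts / x$genes$exonic_length
  tot <- colSums(rate)
  if (any(tot == 0)) warn(paste0(sum(tot == 0), " cell(s) with all-zero counts; tpm set to 0"))
  tpm <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm[, tot == 0] <- 0
  dimnames(tpm) <- dimnames(x$counts)
  x$layers$tpm <- tpm
  x
}

#' Expressed-gene mask
#'
#' A gene is expressed in a cell when its rpkm is at or above `threshold`
#' (boundary inclusive: rpkm exactly 0.1 counts as expressed).
#'
#' @param x An [expr_matrix()] with the rpkm layer filled.
#' @param threshold rpkm cutoff (default 0.1).
#' @return Logical genes x cells matrix.
#' @export
flag_expressed <- function(x, threshold = 0.1) {
  if (is.null(x$layers$rpkm)) abort("rpkm layer not filled; run compute_rpkm() first")
  x$layers$rpkm >= threshold
}
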