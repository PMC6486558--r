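#' Align an expression matrix onto a reference gene space
#'
#' Reorders and subsets the rows of a genes-by-cells matrix so that the
#' output row order equals the gene space exactly: genes of `m` absent from
#' the space are dropped, genes of the space absent from `m` become all-zero
#' rows. This is how an arbitrary dataset is mapped onto the fixed input
#' nodes of a trained classifier. An optional homolog map translates the
#' dataset's symbols (e.g. mouse) to the reference symbols before matching.
#'
#' If fewer than `min_overlap` of the reference genes are found in `m` the
#' call fails: such a low hit rate almost always means the wrong species or
#' the wrong annotation, and silently feeding mostly-zero profiles to a
#' classifier would produce garbage labels.
#'
#' @param m Genes-by-cells count matrix with gene symbols as rownames.
#' @param gs A [gene_space()].
#' @param homolog_map Optional two-column data frame (`from`, `to`) mapping
#'   the dataset's symbols to reference symbols.
#' @param min_overlap Minimum fraction of reference genes that must be
#'   present in `m` (default 0.2).
#' @return A genes-by-cells sparse matrix whose rownames equal `gs` in
#'   order.
#' @export
align_to_gene_space <- function(m, gs, homolog_map = NULL, min_overlap = 0.2) {
  gs <- gene_space(gs)
  syms <- normalize_symbols(rownames(m))
  if (!is.null(homolog_map)) {
    if (ncol(homolog_map) < 2L) stopf("homolog_map needs two columns")
    from <- normalize_symbols(homolog_map[[1L]])
    to <- normalize_symbols(homolog_map[[2L]])
    hit <- match(syms, from)
    syms[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  idx <- match(unclass(gs), syms)
  found <- sum(!is.na(idx))
  if (found < min_overlap * length(gs)) {
    stopf(paste0("only %d of %d reference genes found (%.1f%% < %.0f%%); ",
                 "wrong species or wrong annotation?"),
          found, length(gs), 100 * found / length(gs), 100 * min_overlap)
  }
  out <- Matrix::Matrix(0, nrow = length(gs), ncol = ncol(m), sparse = TRUE)
  out <- methods::as(out, "CsparseMatrix")
  present <- which(!is.na(idx))
  out[present, ] <- m[idx[present], , drop = FALSE]
  dimnames(out) <- list(unclass(gs), colnames(m))
  methods::as(out, "CsparseMatrix")
}
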