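#' Read a UMI-count expression matrix
#'
#' Reads either a CellRanger-style Matrix Market triplet directory
#' (`matrix.mtx` plus a `genes.tsv`/`features.tsv` sidecar and a
#' `barcodes.tsv` sidecar, optionally gzipped) or a dense delimited table
#' with gene rows, a first column of gene symbols and a header of cell IDs.
#' The result is always oriented genes-by-cells regardless of the on-disk
#' orientation (decided from the sidecar lengths for the MTX dialect).
#'
#' Gene symbols are normalized (uppercase, whitespace stripped); rows that
#' collide after normalization are collapsed by element-wise maximum, which
#' preserves presence/absence — the only signal used downstream.
#'
#' @param path For `format = "mtx"`, a directory containing the triplet
#'   files (or a path to `matrix.mtx` itself); for `format = "dense"`, a
#'   TSV/CSV file. `"auto"` picks by inspecting the path.
#' @param format One of `"auto"`, `"mtx"`, `"dense"`.
#' @param on_noninteger What to do with fractional counts: `"floor"` (warn
#'   and truncate, the default) or `"error"`.
#' @return A sparse `dgCMatrix` of non-negative integer counts with gene
#'   symbols as rownames and cell IDs as colnames.
#' @examples
#' d <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2", "A\t0\t2", "B\t5\t0", "C\t1\t1"), d)
#' m <- read_expression_matrix(d)
#' dim(m)
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "mtx", "dense"),
                                   on_noninteger = c("floor", "error")) {
  format <- match.arg(format)
  on_noninteger <- match.arg(on_noninteger)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "dense"
  }
  if (format == "mtx") {
    read_mtx_triplet(path, on_noninteger)
  } else {
    read_dense_matrix(path, on_noninteger)
  }
}

find_sidecar <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_mtx_triplet <- function(path, on_noninteger) {
  if (dir.exists(path)) {
    dir <- path
    mtx <- find_sidecar(dir, c("matrix.mtx", "matrix.mtx.gz"))
    if (is.null(mtx)) stopf("no matrix.mtx[.gz] in %s", dir)
  } else {
    mtx <- path
    dir <- dirname(path)
  }
  if (!file.exists(mtx)) stopf("matrix file not found: %s", mtx)
  genes_f <- find_sidecar(dir, c("genes.tsv", "genes.tsv.gz",
                                 "features.tsv", "features.tsv.gz"))
  cells_f <- find_sidecar(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(genes_f)) stopf("missing genes/features sidecar in %s", dir)
  if (is.null(cells_f)) stopf("missing barcodes sidecar in %s", dir)

  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stopf("malformed MTX file %s: %s", mtx,
                                          conditionMessage(e)))
  gene_tab <- utils::read.table(genes_f, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
  # features file may be (id), or (id, symbol[, type]); use the symbol column
  genes <- if (ncol(gene_tab) >= 2L) gene_tab[[2L]] else gene_tab[[1L]]
  cells <- readLines(cells_f, warn = FALSE)

  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    # genes are rows, nothing to do
  } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stopf("MTX header is %d x %d but sidecars list %d genes and %d cells",
          nrow(m), ncol(m), length(genes), length(cells))
  }
  expression_matrix(m, genes, cells, on_noninteger = on_noninteger)
}

read_dense_matrix <- function(path, on_noninteger) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, quote = "")
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  expression_matrix(m, rownames(tab), colnames(tab),
                    on_noninteger = on_noninteger)
}

# Shared constructor/validator: normalizes gene symbols, collapses duplicate
# rows by element-wise max, enforces non-negative integral counts.
expression_matrix <- function(counts, genes, cells,
                              on_noninteger = c("floor", "error")) {
  on_noninteger <- match.arg(on_noninteger)
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(genes)) {
    stopf("%d gene symbols for %d matrix rows", length(genes), nrow(counts))
  }
  if (ncol(counts) != length(cells)) {
    stopf("%d cell IDs for %d matrix columns", length(cells), ncol(counts))
  }
  if (anyDuplicated(cells)) stopf("duplicate cell IDs")
  x <- counts@x
  if (length(x) && min(x) < 0) stopf("negative counts in expression matrix")
  if (length(x) && any(x != floor(x))) {
    if (on_noninteger == "error") stopf("non-integer counts in matrix")
    warnf("non-integer counts floored to integers")
    counts@x <- floor(x)
    counts <- Matrix::drop0(counts)
  }
  genes <- normalize_symbols(genes)
  if (anyDuplicated(genes)) {
    # collapse duplicated symbols by element-wise max (presence-preserving)
    keep <- !duplicated(genes)
    dup_syms <- unique(genes[duplicated(genes)])
    out <- counts[keep, , drop = FALSE]
    rownames(out) <- genes[keep]
    for (s in dup_syms) {
      rows <- which(genes == s)
      collapsed <- counts[rows[1L], ]
      for (r in rows[-1L]) collapsed <- pmax(collapsed, counts[r, ])
      out[match(s, rownames(out)), ] <- collapsed
    }
    counts <- out
  } else {
    rownames(counts) <- genes
  }
  colnames(counts) <- cells
  counts
}

#' Write an expression matrix
#'
#' Writes the MTX triplet dialect (a directory with `matrix.mtx`,
#' `genes.tsv`, `barcodes.tsv`) or a dense delimited table, the same
#' dialects [read_expression_matrix()] accepts, so write/read round-trips
#' are lossless.
#'
#' @param m Genes-by-cells count matrix with dimnames.
#' @param path Target directory (mtx) or file (dense).
#' @param format `"mtx"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, format = c("mtx", "dense")) {
  format <- match.arg(format)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stopf("matrix must carry gene rownames and cell colnames")
  }
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sp <- Matrix::Matrix(m, sparse = TRUE)
    sp <- methods::as(methods::as(methods::as(sp, "dMatrix"),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(id = rownames(m), symbol = rownames(m)),
      file.path(path, "genes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else {
    dm <- as.matrix(m)
    tab <- data.frame(gene = rownames(m), dm, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a two-column cell label table
#'
#' @param path TSV with columns `cell_id` and `label` (header optional but
#'   recommended).
#' @return A tibble with character columns `cell_id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("label file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^cell_id\t", first)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stopf("label table needs two columns (cell_id, label)")
  tibble::tibble(cell_id = tab[[1L]], label = tab[[2L]])
}

#' @rdname read_labels
#' @param labels A data frame with `cell_id` and `label` columns.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("cell_id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
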