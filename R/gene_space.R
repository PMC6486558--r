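#' Define a reference gene space
#'
#' A gene space is the ordered list of gene symbols that defines the input
#' nodes of a classifier. Once a model is trained its gene space is fixed:
#' every dataset is aligned onto it before binarization, so the i-th input
#' node always means the same gene. The reference space used for published
#' mouse/human models contained 16,013 human--mouse homologous genes; any
#' symbol list works.
#'
#' Symbols are normalized (uppercased, internal whitespace stripped) so that
#' human and mouse orthograph variants of the same symbol (e.g. `CD3D` /
#' `Cd3d`) match.
#'
#' @param symbols Character vector of gene symbols.
#' @return An object of class `gene_space`: a character vector of unique
#'   normalized symbols in their given order.
#' @examples
#' gs <- gene_space(c("Cd3d", "CD79A", "Kdr"))
#' length(gs)
#' @export
gene_space <- function(symbols) {
  symbols <- normalize_symbols(symbols)
  symbols <- symbols[nzchar(symbols)]
  if (length(symbols) == 0L) stopf("gene space is empty")
  if (anyDuplicated(symbols)) {
    symbols <- unique(symbols)
  }
  structure(symbols, class = "gene_space")
}

#' @export
print.gene_space <- function(x, ...) {
  cat(sprintf("<gene_space> %d genes: %s%s\n", length(x),
              paste(head(unclass(x), 5L), collapse = ", "),
              if (length(x) > 5L) ", ..." else ""))
  invisible(x)
}

#' Read / write a gene space as one symbol per line
#'
#' @param path Path to a plain-text file with one gene symbol per line.
#' @return `read_gene_space()` returns a [gene_space()]; `write_gene_space()`
#'   returns `path` invisibly.
#' @export
read_gene_space <- function(path) {
  if (!file.exists(path)) stopf("gene-space file not found: %s", path)
  gene_space(readLines(path, warn = FALSE))
}

#' @rdname read_gene_space
#' @param gs A [gene_space()].
#' @export
write_gene_space <- function(gs, path) {
  writeLines(unclass(gene_space(gs)), path)
  invisible(path)
}

# Stable content hash used to detect gene-space mismatches at predict time.
gene_space_hash <- function(gs) {
  s <- paste(unclass(gs), collapse = "\n")
  # FNV-1a 32-bit over the UTF-8 bytes; cheap, dependency-free.
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
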