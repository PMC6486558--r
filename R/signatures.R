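#' Presence/absence contingency table for one (gene, type) pair
#'
#' Tallies the 2x2 table of gene presence (present/absent) against type
#' membership (in-type/out-of-type) over all cells — the sufficient
#' statistic for the information-gain ranking of signature genes.
#'
#' @param x Cells-by-genes binary matrix.
#' @param labels Cell-type labels, one per row of `x`.
#' @param type Cell-type name defining the in-type group.
#' @param gene Gene symbol (a column of `x`).
#' @return A named integer vector `c(n11, n10, n01, n00)`: in-type present,
#'   in-type absent, out-of-type present, out-of-type absent.
#' @export
contingency_table <- function(x, labels, type, gene) {
  x <- validate_binary_matrix(x)
  labels <- as_label_vector(labels, rownames(x))
  if (!type %in% labels) stopf("type '%s' not present in labels", type)
  gene <- normalize_symbols(gene)
  j <- match(gene, colnames(x))
  if (is.na(j)) stopf("gene '%s' not in the matrix's gene space", gene)
  in_type <- labels == type
  g <- x[, j] > 0
  c(n11 = sum(in_type & g), n10 = sum(in_type & !g),
    n01 = sum(!in_type & g), n00 = sum(!in_type & !g))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a gene's presence for a cell type
#'
#' The reduction in entropy of binary type membership T (cell in type
#' vs not) obtained by observing the gene's binary status G (present vs
#' absent):
#' \deqn{Gain = H(T) - \sum_{j \in \{present, absent\}} P(G = j)\, H(T \mid G = j)}
#' which for two binary variables equals the mutual information I(T; G).
#' Computed in bits (base-2 logarithm) with the convention 0·log 0 = 0;
#' the base does not affect rankings. Gains are clipped at 0 against
#' floating-point rounding.
#'
#' @param t A contingency table from [contingency_table()] — a numeric
#'   vector `(n11, n10, n01, n00)`.
#' @return Gain in bits, in `[0, min(H(T), 1)]`.
#' @examples
#' # a gene present in exactly the 50 in-type cells of 100 splits T perfectly
#' information_gain(c(n11 = 50, n10 = 0, n01 = 0, n00 = 50))  # 1 bit
#' @export
information_gain <- function(t) {
  t <- as.numeric(t)
  if (length(t) != 4L || any(t < 0)) stopf("need 4 non-negative counts")
  n <- sum(t)
  if (n == 0) stopf("empty contingency table")
  n11 <- t[1L]; n10 <- t[2L]; n01 <- t[3L]; n00 <- t[4L]
  h_type <- entropy_bits(c(n11 + n10, n01 + n00) / n)
  n_present <- n11 + n01
  n_absent <- n10 + n00
  h_cond <- 0
  if (n_present > 0) {
    h_cond <- h_cond + (n_present / n) * entropy_bits(c(n11, n01) / n_present)
  }
  if (n_absent > 0) {
    h_cond <- h_cond + (n_absent / n) * entropy_bits(c(n10, n00) / n_absent)
  }
  max(h_type - h_cond, 0)
}

#' Rank signature genes for a cell type by information gain
#'
#' Scores every gene in the matrix's gene space by how much its
#' presence/absence status reduces uncertainty about membership in the
#' given type (one-vs-rest), and returns the top `n` (50 by default, the
#' conventional signature size). Ties break lexicographically by gene
#' symbol so rankings are deterministic.
#'
#' @param x Cells-by-genes binary matrix.
#' @param labels Cell-type labels, one per row of `x`.
#' @param type Cell type to rank genes for.
#' @param n Number of top genes to return (default 50); if larger than the
#'   gene space, all genes are returned with a warning.
#' @return A tibble with columns `rank`, `gene`, `gain_bits`, `n11`,
#'   `n10`, `n01`, `n00`, sorted by non-increasing gain.
#' @export
top_signature_genes <- function(x, labels, type, n = 50L) {
  x <- validate_binary_matrix(x)
  labels <- as_label_vector(labels, rownames(x))
  if (!type %in% labels) stopf("type '%s' not present in labels", type)
  genes <- colnames(x) %||% sprintf("G%d", seq_len(ncol(x)))
  in_type <- labels == type
  n_in <- sum(in_type)
  n_out <- sum(!in_type)
  total <- n_in + n_out

  # vectorized 2x2 tallies over all genes at once
  n11 <- colSums(x[in_type, , drop = FALSE])
  n01 <- colSums(x[!in_type, , drop = FALSE])
  n10 <- n_in - n11
  n00 <- n_out - n01

  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  h_type <- entropy_bits(c(n_in, n_out) / total)
  n_present <- n11 + n01
  n_absent <- n10 + n00
  h_present <- -(plogp(ifelse(n_present > 0, n11 / n_present, 0)) +
                 plogp(ifelse(n_present > 0, n01 / n_present, 0)))
  h_absent <- -(plogp(ifelse(n_absent > 0, n10 / n_absent, 0)) +
                plogp(ifelse(n_absent > 0, n00 / n_absent, 0)))
  gain <- h_type - (n_present / total) * h_present -
    (n_absent / total) * h_absent
  gain <- pmax(gain, 0)

  out <- tibble::tibble(gene = genes, gain_bits = unname(gain),
                        n11 = as.integer(n11), n10 = as.integer(n10),
                        n01 = as.integer(n01), n00 = as.integer(n00))
  out <- dplyr::arrange(out, dplyr::desc(.data$gain_bits), .data$gene)
  if (n > nrow(out)) {
    warnf("requested %d genes but the gene space has only %d", n, nrow(out))
    n <- nrow(out)
  }
  out <- dplyr::mutate(head(out, n), rank = dplyr::row_number(),
                       .before = 1L)
  out
}
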