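#' Binarize UMI counts to presence/absence profiles
#'
#' Converts a genes-by-cells count matrix (already aligned to a gene space)
#' into the cells-by-genes 0/1 matrix the classifier consumes: a gene is
#' *present* in a cell iff its UMI count is positive. No threshold above 1
#' is applied — UMI platforms are digital, so a single molecule is evidence
#' of expression, and the binary signal is what makes profiles comparable
#' across platforms and sequencing depths.
#'
#' @param m Genes-by-cells matrix of non-negative counts.
#' @return A dense base matrix of 0/1 values, cells in rows (sample
#'   convention for the network), genes in columns.
#' @examples
#' m <- matrix(c(0, 1, 7, 0), nrow = 2,
#'             dimnames = list(c("A", "B"), c("c1", "c2")))
#' binarize(m)
#' @export
binarize <- function(m) {
  if (any(m < 0)) stopf("negative counts cannot be binarized")
  b <- t(as.matrix(m > 0)) * 1
  dimnames(b) <- list(colnames(m), rownames(m))
  b
}

#' Synthesize "unknown"-class profiles by within-cell gene shuffling
#'
#' Draws `n` source profiles (with replacement) and permutes each one's
#' values across gene positions. A shuffled profile keeps its library
#' complexity (the number of present genes is unchanged) but loses all
#' co-expression structure, so it resembles no real cell type; such
#' profiles are always labeled with the catalog's unknown class during
#' training, teaching the network an explicit "none of the above" output.
#'
#' @param source Cells-by-genes binary matrix (e.g. from [binarize()]).
#' @param n Number of synthetic profiles to create.
#' @param seed Integer seed; the output is reproducible from it.
#' @return A cells-by-genes binary matrix with `n` rows named
#'   `synthetic_unknown_<i>`.
#' @export
synthesize_unknown <- function(source, n, seed = NULL) {
  if (nrow(source) == 0L) stopf("source matrix is empty")
  if (n < 1L) stopf("n must be at least 1")
  p <- ncol(source)
  with_seed(seed, {
    picks <- sample.int(nrow(source), n, replace = TRUE)
    out <- matrix(0, nrow = n, ncol = p,
                  dimnames = list(sprintf("synthetic_unknown_%d", seq_len(n)),
                                  colnames(source)))
    for (i in seq_len(n)) {
      out[i, ] <- source[picks[i], sample.int(p)]
    }
    out
  })
}

#' Balanced inverse-frequency class weights
#'
#' Cell-type sample sizes in atlas-scale training data span orders of
#' magnitude; unweighted cross-entropy would let the large types dominate
#' and under-represent the small ones. Each class receives weight
#' \eqn{w_c = N / (K \cdot N_c)} where \eqn{N} is the number of cells,
#' \eqn{K} the number of classes present and \eqn{N_c} the class size, so
#' every class contributes equally to the loss and
#' \eqn{\sum_c w_c N_c = N} holds exactly.
#'
#' @param labels Character vector (or `cell_id`/`label` table) of training
#'   labels.
#' @param catalog A [cell_type_catalog()]; all labels must belong to it.
#' @param missing What to do with catalog classes that have no example:
#'   `"error"` (default) or `"drop"` (excluded from the weight table).
#' @return A tibble with columns `class`, `n_cells`, `weight`, one row per
#'   class present, in catalog order.
#' @examples
#' cat2 <- cell_type_catalog(c("A", "B"))
#' compute_class_weights(c(rep("A", 100), rep("B", 50), "Unknown"),
#'                       catalog = cat2, missing = "drop")
#' @export
compute_class_weights <- function(labels, catalog, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  labels <- as_label_vector(labels)
  if (length(labels) == 0L) stopf("no labels supplied")
  catalog_index(labels, catalog)
  counts <- table(factor(labels, levels = catalog$classes))
  absent <- names(counts)[counts == 0L]
  if (length(absent) && missing == "error") {
    stopf("catalog class(es) with no example: %s",
          paste(head(absent, 5L), collapse = ", "))
  }
  present <- counts[counts > 0L]
  n_total <- sum(present)
  k <- length(present)
  tibble::tibble(
    class = names(present),
    n_cells = as.integer(present),
    weight = n_total / (k * as.numeric(present))
  )
}

# Map a class-weight tibble onto a label vector -> per-sample weights.
sample_weights <- function(labels, class_weights) {
  if (is.null(class_weights)) return(rep(1, length(labels)))
  w <- class_weights$weight[match(labels, class_weights$class)]
  if (anyNA(w)) {
    stopf("label(s) without a class weight: %s",
          paste(head(unique(labels[is.na(w)]), 5L), collapse = ", "))
  }
  w
}
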