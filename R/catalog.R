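#' Build a cell-type catalog
#'
#' The catalog is the ordered set of cell types a classifier can output.
#' It always ends with a mandatory `"Unknown"` class: profiles that belong to
#' none of the known types (including synthetic shuffled profiles used in
#' training) are assigned there explicitly, rather than through a confidence
#' cutoff. A classifier for K known types therefore has K + 1 output nodes
#' (e.g. 30+1 or 37+1 in the published mouse models).
#'
#' @param known_types Character vector of known cell-type names, in the order
#'   the output nodes should take.
#' @param unknown_label Name of the sentinel class, `"Unknown"` by default.
#' @return An object of class `cell_type_catalog` with fields `known`,
#'   `unknown_label` and `classes` (known types followed by the unknown
#'   label).
#' @examples
#' cat37 <- cell_type_catalog(paste0("T", 1:37))
#' length(cat37$classes)  # 38 output nodes
#' @export
cell_type_catalog <- function(known_types, unknown_label = "Unknown") {
  known_types <- as.character(known_types)
  if (length(known_types) == 0L) stopf("catalog needs at least one known type")
  if (anyDuplicated(known_types)) stopf("duplicate cell-type names in catalog")
  if (unknown_label %in% known_types) {
    stopf("'%s' is reserved for the unknown class", unknown_label)
  }
  structure(
    list(
      known = known_types,
      unknown_label = unknown_label,
      classes = c(known_types, unknown_label)
    ),
    class = "cell_type_catalog"
  )
}

#' @export
print.cell_type_catalog <- function(x, ...) {
  cat(sprintf("<cell_type_catalog> %d known types + '%s' (%d outputs)\n",
              length(x$known), x$unknown_label, length(x$classes)))
  invisible(x)
}

#' @export
length.cell_type_catalog <- function(x) length(x$classes)

# Validate a label vector against a catalog; returns integer class indices.
catalog_index <- function(labels, catalog) {
  idx <- match(labels, catalog$classes)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stopf("label(s) not in catalog: %s", paste(head(bad, 5L), collapse = ", "))
  }
  idx
}
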