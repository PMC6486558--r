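#' Tidy a trained classifier's training history
#'
#' @param x A `scident_model`.
#' @param ... Unused.
#' @return A tibble with one row per completed epoch (loss, accuracy and
#'   the validation or replay-pool counterparts, depending on how the
#'   model was last trained). Empty if the model is untrained.
#' @export
tidy.scident_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer())
}

#' One-row summary of a classifier
#'
#' @param x A `scident_model`.
#' @param ... Unused.
#' @return A tibble with the version tag, gene-space size, catalog sizes,
#'   parameter count, epochs trained and final validation metrics.
#' @export
glance.scident_model <- function(x, ...) {
  n_par <- sum(vapply(x$weights, function(l) length(l$W) + length(l$b),
                      numeric(1)))
  h <- x$history
  tibble::tibble(
    version = x$version,
    n_genes = x$config$input_size,
    n_known_types = length(x$catalog$known),
    n_classes = length(x$catalog$classes),
    n_parameters = n_par,
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    final_val_loss = if (!is.null(h) && "val_loss" %in% names(h) && nrow(h))
      h$val_loss[nrow(h)] else NA_real_,
    final_val_accuracy = if (!is.null(h) && "val_accuracy" %in% names(h) &&
                             nrow(h)) h$val_accuracy[nrow(h)] else NA_real_
  )
}

#' Tidy a confusion matrix into long form
#'
#' @param x A `scident_confusion` from [confusion_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `ref`, `pred`, `n` (all cells, including
#'   zero counts, so marginals are easy to recompute).
#' @export
tidy.scident_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    ref = rep(rownames(m), times = ncol(m)),
    pred = rep(colnames(m), each = nrow(m)),
    n = as.integer(m)
  )
}

#' @rdname tidy.scident_confusion
#' @export
glance.scident_confusion <- function(x, ...) {
  m <- unclass(x)
  total <- sum(m)
  tibble::tibble(
    n_cells = total,
    n_classes = nrow(m),
    concordance = if (total > 0) sum(diag(m)) / total else NA_real_
  )
}
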