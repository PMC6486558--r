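#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a classifier's training curves
#'
#' Training and validation (or replay-pool) loss per epoch — the gap
#' between the two curves is the overfitting signal early stopping acts
#' on.
#'
#' @param object A trained `scident_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scident_model <- function(object, ...) {
  h <- tidy(object)
  if (nrow(h) == 0L) stopf("model has no training history to plot")
  loss_cols <- intersect(c("loss", "val_loss", "replay_loss"), names(h))
  long <- tidyr::pivot_longer(h[, c("epoch", loss_cols)], -"epoch",
                              names_to = "series", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL,
                  title = sprintf("Training history (%s)", object$version)) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object A `scident_confusion` from [confusion_matrix()].
#' @param normalize Show row-normalized fractions instead of counts
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scident_confusion <- function(object, normalize = TRUE, ...) {
  d <- tidy(object)
  if (normalize) {
    d <- dplyr::mutate(dplyr::group_by(d, .data$ref),
                       value = ifelse(sum(.data$n) > 0,
                                      .data$n / sum(.data$n), 0))
    d <- dplyr::ungroup(d)
    fill_lab <- "fraction of reference"
  } else {
    d <- dplyr::mutate(d, value = .data$n)
    fill_lab <- "cells"
  }
  classes <- rownames(unclass(object))
  d$ref <- factor(d$ref, levels = rev(classes))
  d$pred <- factor(d$pred, levels = classes)
  ggplot2::ggplot(d, ggplot2::aes(.data$pred, .data$ref,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 name = fill_lab) +
    ggplot2::labs(x = "predicted", y = "reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a signature-gene ranking
#'
#' @param ranking A tibble from [top_signature_genes()].
#' @param n Genes to display (default 20).
#' @return A ggplot of information gain per gene.
#' @export
plot_signature_genes <- function(ranking, n = 20L) {
  d <- head(ranking, n)
  d$gene <- factor(d$gene, levels = rev(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(.data$gain_bits, .data$gene)) +
    ggplot2::geom_col(fill = "#08519c") +
    ggplot2::labs(x = "information gain (bits)", y = NULL) +
    ggplot2::theme_minimal()
}
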