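#' Concordance between predicted and reference labels
#'
#' The fraction of cells whose predicted type agrees with the reference
#' annotation. With `scope = "known"` the denominator is restricted to
#' cells whose reference label is a known (non-Unknown) type — the form in
#' which headline concordances on annotated atlases are quoted. A rename
#' table maps one taxonomy's names onto the other's before comparison
#' (applied to `ref`); no fuzzy matching is attempted.
#'
#' @param pred,ref Equal-length label vectors.
#' @param scope `"all"` or `"known"`.
#' @param unknown_label Reference label excluded under `scope = "known"`.
#' @param rename Optional two-column data frame (`from`, `to`) applied to
#'   `ref` before comparison.
#' @return A single fraction in `[0, 1]`.
#' @export
concordance <- function(pred, ref, scope = c("all", "known"),
                        unknown_label = "Unknown", rename = NULL) {
  scope <- match.arg(scope)
  pred <- as.character(pred); ref <- as.character(ref)
  if (length(pred) != length(ref)) stopf("pred and ref differ in length")
  if (length(pred) == 0L) stopf("no cells to compare")
  if (!is.null(rename)) {
    hit <- match(ref, as.character(rename[[1L]]))
    ref[!is.na(hit)] <- as.character(rename[[2L]])[hit[!is.na(hit)]]
  }
  if (scope == "known") {
    keep <- ref != unknown_label
    if (!any(keep)) stopf("no cells with a known reference label")
    pred <- pred[keep]; ref <- ref[keep]
  }
  mean(pred == ref)
}

#' Confusion matrix over a catalog
#'
#' Cross-tabulates reference labels (rows) against predictions (columns)
#' over the catalog's class order; correct calls lie on the diagonal, and
#' `trace/total` equals [concordance()] with `scope = "all"` exactly.
#'
#' @param pred,ref Label vectors of equal length.
#' @param catalog A [cell_type_catalog()] (or character vector of classes)
#'   covering all labels.
#' @return An object of class `scident_confusion`: a square integer matrix
#'   with a `classes` attribute. Use [tidy()] for a long tibble.
#' @export
confusion_matrix <- function(pred, ref, catalog) {
  classes <- if (inherits(catalog, "cell_type_catalog")) catalog$classes
             else as.character(catalog)
  pred <- as.character(pred); ref <- as.character(ref)
  if (length(pred) != length(ref)) stopf("pred and ref differ in length")
  bad <- setdiff(unique(c(pred, ref)), classes)
  if (length(bad)) stopf("label(s) not in catalog: %s",
                         paste(head(bad, 5L), collapse = ", "))
  m <- table(factor(ref, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(ref = classes, pred = classes))
  structure(m, class = c("scident_confusion", class(m)))
}

#' @export
print.scident_confusion <- function(x, ...) {
  total <- sum(x)
  conc <- if (total > 0) sum(diag(unclass(x))) / total else NA_real_
  cat(sprintf("<confusion matrix> %d classes, %d cells, concordance %.3f\n",
              nrow(x), total, conc))
  print(unclass(x))
  invisible(x)
}

#' Label-transition table between two labelings
#'
#' Cross-tabulates two labelings of the same cells (e.g. predictions of a
#' model before and after an upgrade), the data behind a Sankey diagram of
#' label flows. Marginal sums reproduce each labeling's class sizes.
#'
#' @param from,to Label vectors over the same cells, same order.
#' @return A tibble with columns `from`, `to`, `n` (only nonzero flows),
#'   sorted by descending `n`.
#' @export
transition_table <- function(from, to) {
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to)) stopf("labelings differ in length")
  tab <- table(from = from, to = to)
  out <- tibble::as_tibble(tab)
  out <- dplyr::filter(out, .data$n > 0)
  dplyr::arrange(out, dplyr::desc(.data$n), .data$from, .data$to)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Randomly divides the cells into k near-equal folds (stratified by class
#' so that small types appear in every test fold, degrading to an
#' unstratified split with a warning when a class has fewer members than
#' k), trains a fresh classifier on k-1 folds and measures concordance on
#' the held-out fold. Fold test sets are disjoint, cover every cell, and
#' differ in size by at most one.
#'
#' @param x Cells-by-genes binary matrix.
#' @param labels Catalog labels, one per row of `x`.
#' @param catalog A [cell_type_catalog()] covering the labels.
#' @param k Number of folds (default 10).
#' @param config A [train_config()] used for every fold.
#' @param hidden_sizes,dropout_rate Architecture for the per-fold models.
#' @param class_weighted Apply balanced class weights per fold (default
#'   `TRUE`).
#' @param seed Integer seed for fold assignment and per-fold training.
#' @return A tibble with columns `fold`, `n_test`, `concordance`; the mean
#'   concordance is attached as attribute `"mean_concordance"` and shown by
#'   `glance()`-style summaries.
#' @export
kfold_cv <- function(x, labels, catalog, k = 10L, config = train_config(),
                     hidden_sizes = c(200L, 100L), dropout_rate = 0.4,
                     seed = NULL) {
  x <- validate_binary_matrix(x)
  labels <- as_label_vector(labels, rownames(x))
  if (k < 2L) stopf("k must be at least 2")
  if (nrow(x) < k) stopf("fewer cells than folds")
  catalog_index(labels, catalog)
  gs <- gene_space(colnames(x) %||% sprintf("G%d", seq_len(ncol(x))))

  folds <- with_seed(seed, assign_folds(labels, k))
  res <- lapply(seq_len(k), function(f) {
    test <- which(folds == f)
    train <- which(folds != f)
    fold_seed <- if (is.null(seed)) NULL else (seed + f) %% .Machine$integer.max
    model <- init_model(catalog, gs, hidden_sizes = hidden_sizes,
                        dropout_rate = dropout_rate, seed = fold_seed)
    cw <- compute_class_weights(labels[train], catalog, missing = "drop")
    cfg <- config
    cfg$seed <- fold_seed
    model <- train_classifier(model, x[train, , drop = FALSE], labels[train],
                              config = cfg, class_weights = cw,
                              keep_replay = FALSE)
    pred <- predict(model, x[test, , drop = FALSE], type = "label")
    tibble::tibble(fold = f, n_test = length(test),
                   concordance = concordance(pred, labels[test]))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "mean_concordance") <- mean(out$concordance)
  out
}

# Stratified fold labels 1..k, balanced overall: per class, members are
# shuffled and dealt round-robin starting from a rotating offset.
assign_folds <- function(labels, k) {
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    warnf("class(es) with fewer than k members; using unstratified folds")
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    return(sample(rep.int(seq_len(k), sizes)))
  }
  folds <- integer(n)
  offset <- 0L
  for (cls in names(counts)) {
    members <- sample(which(labels == cls))
    folds[members] <- ((seq_along(members) - 1L + offset) %% k) + 1L
    offset <- (offset + length(members)) %% k
  }
  folds
}
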