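#' Configuration for the synthetic binary profile generator
#'
#' The generator emulates the structure the classifier assumes in
#' binarized UMI data: each cell type owns a block of marker genes that
#' are present with high probability in that type and at a low background
#' rate elsewhere; non-marker background genes are present at a uniform
#' low rate; and a global extra-dropout probability zeroes present calls
#' to mimic technical signal loss. Genes are independent Bernoulli
#' variables given the type — enough to exercise every pipeline stage,
#' though real data carry co-expression, depth and batch structure this
#' deliberately omits.
#'
#' @param n_types Number of cell types (default 6).
#' @param markers_per_type Marker genes owned by each type (default 40).
#' @param n_background_genes Non-marker genes (default 1500).
#' @param p_marker_on Presence probability of a marker in its own type
#'   (default 0.8).
#' @param p_marker_off Presence probability of a marker in other types
#'   (default 0.05).
#' @param p_background_on Background-gene presence probability (default
#'   0.10).
#' @param cells_per_type Cells per type (default 500); a vector of length
#'   `n_types` gives imbalanced classes.
#' @param dropout_extra Extra zeroing probability applied to every
#'   presence call (default 0.1).
#' @param seed Integer seed; the same seed yields a bit-identical dataset.
#' @return A `synthetic_config` list. The implied gene space has
#'   `n_types * markers_per_type + n_background_genes` genes.
#' @export
synthetic_config <- function(n_types = 6L, markers_per_type = 40L,
                             n_background_genes = 1500L,
                             p_marker_on = 0.8, p_marker_off = 0.05,
                             p_background_on = 0.10,
                             cells_per_type = 500L,
                             dropout_extra = 0.1, seed = NULL) {
  stopifnot(n_types >= 1L, markers_per_type >= 1L, n_background_genes >= 0L,
            p_marker_on >= 0, p_marker_on <= 1,
            p_marker_off >= 0, p_marker_off <= 1,
            p_background_on >= 0, p_background_on <= 1,
            dropout_extra >= 0, dropout_extra < 1,
            all(cells_per_type >= 1L))
  if (p_marker_on <= p_marker_off) {
    stopf("p_marker_on must exceed p_marker_off for marker structure to exist")
  }
  if (length(cells_per_type) == 1L) {
    cells_per_type <- rep(as.integer(cells_per_type), n_types)
  }
  if (length(cells_per_type) != n_types) {
    stopf("cells_per_type must have length 1 or n_types")
  }
  structure(list(n_types = as.integer(n_types),
                 markers_per_type = as.integer(markers_per_type),
                 n_background_genes = as.integer(n_background_genes),
                 p_marker_on = p_marker_on, p_marker_off = p_marker_off,
                 p_background_on = p_background_on,
                 cells_per_type = as.integer(cells_per_type),
                 dropout_extra = dropout_extra,
                 seed = seed),
            class = "synthetic_config")
}

#' Generate a labeled synthetic binary dataset
#'
#' Draws cells-by-genes 0/1 profiles under a [synthetic_config()]: a cell
#' of type t has each of t's markers present with probability
#' `p_marker_on * (1 - dropout_extra)`, foreign markers with
#' `p_marker_off * (1 - dropout_extra)` and background genes with
#' `p_background_on * (1 - dropout_extra)`. Types are named `Type1..K`,
#' markers `M<type>_<i>`, background genes `BG<i>`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `x` (binary matrix, cells x genes), `labels`
#'   (tibble `cell_id`, `label`), `marker_map` (tibble `gene`, `type`),
#'   `catalog` (a [cell_type_catalog()] of the generated types) and
#'   `config`.
#' @export
generate_labeled_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  types <- sprintf("Type%d", seq_len(cfg$n_types))
  marker_genes <- unlist(lapply(seq_len(cfg$n_types), function(t) {
    sprintf("M%d_%d", t, seq_len(cfg$markers_per_type))
  }))
  bg_genes <- if (cfg$n_background_genes > 0L) {
    sprintf("BG%d", seq_len(cfg$n_background_genes))
  } else {
    character(0)
  }
  genes <- c(marker_genes, bg_genes)
  p_gene <- matrix(cfg$p_background_on, nrow = cfg$n_types,
                   ncol = length(genes))
  for (t in seq_len(cfg$n_types)) {
    marker_cols <- seq_len(cfg$markers_per_type) +
      (t - 1L) * cfg$markers_per_type
    p_gene[t, seq_along(marker_genes)] <- cfg$p_marker_off
    p_gene[t, marker_cols] <- cfg$p_marker_on
  }
  p_gene <- p_gene * (1 - cfg$dropout_extra)

  n_cells <- sum(cfg$cells_per_type)
  labels <- rep(types, times = cfg$cells_per_type)
  x <- with_seed(cfg$seed, {
    m <- matrix(0, nrow = n_cells, ncol = length(genes))
    row <- 1L
    for (t in seq_len(cfg$n_types)) {
      nt <- cfg$cells_per_type[t]
      block <- matrix(runif(nt * length(genes)), nrow = nt)
      m[row:(row + nt - 1L), ] <- (block < matrix(p_gene[t, ], nrow = nt,
                                                  ncol = length(genes),
                                                  byrow = TRUE)) * 1
      row <- row + nt
    }
    m
  })
  cell_ids <- sprintf("cell_%d", seq_len(n_cells))
  dimnames(x) <- list(cell_ids, normalize_symbols(genes))
  list(
    x = x,
    labels = tibble::tibble(cell_id = cell_ids, label = labels),
    marker_map = tibble::tibble(
      gene = normalize_symbols(marker_genes),
      type = rep(types, each = cfg$markers_per_type)
    ),
    catalog = cell_type_catalog(types),
    config = cfg
  )
}

#' Generate a catalog-upgrade benchmark
#'
#' Builds the data for the two upgrade protocols on one consistent gene
#' space. The base (phase-1) training set covers `cfg$n_types` "old" types
#' plus shuffled synthetic unknowns; a second set contains `n_new_types` unseen
#' types whose cells are labeled with the catalog's Unknown class in
#' phase-1 ground truth and with their specific names in phase-2; held-out
#' test sets are produced for both phases.
#'
#' @param cfg A [synthetic_config()] describing the *old* types; the new
#'   types reuse its marker geometry, so the full gene space has
#'   `(n_types + n_new_types) * markers_per_type + n_background_genes`
#'   genes.
#' @param n_new_types Number of unseen types in the second set (default 2).
#' @param n_unknown Synthetic shuffled-unknown training cells added to the
#'   base set (default 500).
#' @param test_fraction Fraction of each phase's cells held out for
#'   testing (default 0.25).
#' @param seed Integer seed.
#' @return A list with elements `base` (list `x`, `labels`, `catalog` —
#'   old types + Unknown, training data including shuffled unknowns),
#'   `base_test` (`x`, `labels` over old types), `new` (`x`,
#'   `labels_phase1` all-Unknown, `labels_phase2` specific, training cells
#'   of the new types), `new_test` (same fields, held-out), `new_types`
#'   (names) and `gene_space`.
#' @export
generate_upgrade_benchmark <- function(cfg = synthetic_config(),
                                       n_new_types = 2L, n_unknown = 500L,
                                       test_fraction = 0.25, seed = NULL) {
  stopifnot(n_new_types >= 1L, test_fraction > 0, test_fraction < 1)
  total_types <- cfg$n_types + n_new_types
  full_cfg <- synthetic_config(
    n_types = total_types,
    markers_per_type = cfg$markers_per_type,
    n_background_genes = cfg$n_background_genes,
    p_marker_on = cfg$p_marker_on, p_marker_off = cfg$p_marker_off,
    p_background_on = cfg$p_background_on,
    cells_per_type = rep(cfg$cells_per_type, length.out = total_types),
    dropout_extra = cfg$dropout_extra,
    seed = if (is.null(seed)) cfg$seed else seed
  )
  ds <- generate_labeled_dataset(full_cfg)
  old_types <- sprintf("Type%d", seq_len(cfg$n_types))
  new_types <- sprintf("Type%d", cfg$n_types + seq_len(n_new_types))
  lab <- ds$labels$label
  split_seed <- if (is.null(seed)) cfg$seed else seed

  with_seed(if (is.null(split_seed)) NULL else split_seed + 1L, {
    is_old <- lab %in% old_types
    test_idx <- unlist(lapply(unique(lab), function(t) {
      members <- which(lab == t)
      sample(members, max(1L, floor(length(members) * test_fraction)))
    }))
    old_train <- setdiff(which(is_old), test_idx)
    old_test <- intersect(which(is_old), test_idx)
    new_train <- setdiff(which(!is_old), test_idx)
    new_test <- intersect(which(!is_old), test_idx)

    base_x <- ds$x[old_train, , drop = FALSE]
    base_labels <- lab[old_train]
    catalog <- cell_type_catalog(old_types)
    if (n_unknown > 0L) {
      unk <- synthesize_unknown(base_x, n_unknown,
                                seed = if (is.null(split_seed)) NULL
                                       else split_seed + 2L)
      base_x <- rbind(base_x, unk)
      base_labels <- c(base_labels, rep(catalog$unknown_label, n_unknown))
    }

    list(
      base = list(x = base_x, labels = base_labels, catalog = catalog),
      base_test = list(x = ds$x[old_test, , drop = FALSE],
                       labels = lab[old_test]),
      new = list(x = ds$x[new_train, , drop = FALSE],
                 labels_phase1 = rep(catalog$unknown_label,
                                     length(new_train)),
                 labels_phase2 = lab[new_train]),
      new_test = list(x = ds$x[new_test, , drop = FALSE],
                      labels_phase1 = rep(catalog$unknown_label,
                                          length(new_test)),
                      labels_phase2 = lab[new_test]),
      new_types = new_types,
      gene_space = gene_space(colnames(ds$x)),
      marker_map = ds$marker_map
    )
  })
}
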