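#' Review (replay) policy for continual learning
#'
#' Training a network on new data alone erodes what it learned before
#' (catastrophic forgetting). Review training counters this by replaying a
#' random sample of cells from the previous training pool after each epoch
#' on the new data; 4000 replayed cells per epoch is the published default.
#' Sampling is without replacement within an epoch and reproducible from
#' `seed`.
#'
#' @param review_size Cells replayed per epoch; 0 disables review.
#' @param seed Integer seed for the replay draws.
#' @return A `review_policy` list.
#' @export
review_policy <- function(review_size = 4000L, seed = NULL) {
  stopifnot(review_size >= 0L)
  structure(list(review_size = as.integer(review_size), seed = seed),
            class = "review_policy")
}

bump_version <- function(v) {
  n <- suppressWarnings(as.integer(sub("^v", "", v)))
  if (is.na(n)) paste0(v, "+1") else sprintf("v%d", n + 1L)
}

# Shared engine for the two upgrade protocols: epochs over the new data,
# each followed by one pass over a fresh review sample from the retained
# pool. No early stopping: upgrades run the requested number of epochs so
# the review schedule is honored exactly.
continual_fit <- function(model, x, labels, config, policy,
                          class_weights = NULL, frozen_layers = integer(0)) {
  x <- validate_binary_matrix(x)
  if (nrow(x) == 0L) stopf("no new training data supplied")
  labels <- as_label_vector(labels, rownames(x))
  check_gene_space_match(model, x)
  y_idx <- catalog_index(labels, model$catalog)
  w_all <- sample_weights(labels, class_weights)

  pool <- model$replay
  review_size <- policy$review_size
  if (review_size > 0L && is.null(pool)) {
    warnf("model carries no replay pool; review training skipped")
    review_size <- 0L
  }
  if (review_size > 0L) {
    review_size <- min(review_size, nrow(pool$x))
    pool_idx <- catalog_index(pool$labels, model$catalog)
    # review draws come from their own seeded stream so the schedule is
    # reproducible from the policy alone
    review_draws <- with_seed(policy$seed, {
      lapply(seq_len(config$max_epochs), function(e) {
        sample.int(nrow(pool$x), review_size, replace = FALSE)
      })
    })
  }

  state <- new.env(parent = emptyenv())
  state$weights <- model$weights
  state$velocity <- lapply(model$weights, function(l) list(W = l$W * 0,
                                                           b = l$b * 0))
  state$dropout_rate <- model$config$dropout_rate

  hist <- NULL
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      sgd_epoch(state, x, y_idx, w_all, config, frozen_layers)
      if (review_size > 0L) {
        ri <- review_draws[[epoch]]
        sgd_epoch(state, pool$x[ri, , drop = FALSE], pool_idx[ri],
                  rep(1, length(ri)), config, frozen_layers)
      }
      tr <- eval_split(state$weights, x, y_idx, w_all)
      rv <- if (review_size > 0L) {
        eval_split(state$weights, pool$x, pool_idx)
      } else {
        list(loss = NA_real_, accuracy = NA_real_)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = tr$loss,
                                     accuracy = tr$accuracy,
                                     replay_loss = rv$loss,
                                     replay_accuracy = rv$accuracy))
    }
  })

  model$weights <- state$weights
  model$history <- if (is.null(hist)) {
    tibble::tibble(epoch = integer(), loss = double(), accuracy = double(),
                   replay_loss = double(), replay_accuracy = double())
  } else {
    tibble::as_tibble(hist)
  }
  # the new data joins the retained pool for future upgrades
  if (!is.null(pool)) {
    model$replay <- list(x = rbind(pool$x, x), labels = c(pool$labels, labels))
  } else {
    model$replay <- list(x = x, labels = labels)
  }
  model
}

#' Online optimization of a trained model
#'
#' Continues training an existing classifier on new data of already-known
#' types without reinitializing its parameters, with review training
#' replaying cells from the retained previous-training pool after each
#' epoch (see [review_policy()]). The catalog is unchanged; new labels
#' outside it are an error — use [expand_catalog()] for new types.
#'
#' @param model A trained `scident_model` (carrying a replay pool).
#' @param x,labels New training profiles (cells-by-genes binary) and their
#'   catalog labels.
#' @param config A [train_config()]; `max_epochs` epochs are run in full.
#' @param policy A [review_policy()].
#' @param class_weights Optional tibble from [compute_class_weights()].
#' @return The updated `scident_model` with a `$history` tibble carrying
#'   per-epoch loss/accuracy on the new data and on the replay pool.
#' @export
online_update <- function(model, x, labels, config = train_config(),
                          policy = review_policy(), class_weights = NULL) {
  stopifnot(inherits(model, "scident_model"))
  labels_chr <- as_label_vector(labels)
  outside <- setdiff(unique(labels_chr), model$catalog$classes)
  if (length(outside)) {
    stopf("label(s) outside the catalog: %s; use expand_catalog() to add new types",
          paste(head(outside, 5L), collapse = ", "))
  }
  continual_fit(model, x, labels, config, policy, class_weights)
}

#' Expand the cell-type catalog by transfer learning
#'
#' Adds new cell types to a trained classifier: the new types are inserted
#' into the catalog just before the terminal Unknown class, the output
#' layer is widened (existing output columns copied, new ones freshly
#' initialized with the standard scheme and zero bias), the first hidden
#' layer is frozen — its learned feature transform is reused unchanged for
#' the new types — and the remaining layers are trained on the combined
#' old+new-type data with review training from the retained pool.
#'
#' @param model A trained `scident_model`.
#' @param new_types Character vector of type names to add; must be disjoint
#'   from the existing catalog.
#' @param x,labels Training profiles and labels over old and new types;
#'   every new type needs at least one example.
#' @param config A [train_config()].
#' @param policy A [review_policy()].
#' @param class_weights Optional tibble from [compute_class_weights()]
#'   built against the *expanded* catalog.
#' @param init_seed Seed for the new output columns' initialization.
#' @return The expanded `scident_model`; its version tag is bumped (v1 ->
#'   v2) and its first-hidden-layer weights are bit-identical to the
#'   input model's.
#' @export
expand_catalog <- function(model, new_types, x, labels,
                           config = train_config(), policy = review_policy(),
                           class_weights = NULL, init_seed = NULL) {
  stopifnot(inherits(model, "scident_model"))
  new_types <- as.character(new_types)
  if (anyDuplicated(new_types)) stopf("duplicate new type names")
  clash <- intersect(new_types, model$catalog$classes)
  if (length(clash)) stopf("type(s) already in catalog: %s",
                           paste(clash, collapse = ", "))
  labels_chr <- as_label_vector(labels)
  for (nt in new_types) {
    if (!nt %in% labels_chr) stopf("no training example for new type '%s'", nt)
  }
  old_catalog <- model$catalog
  new_catalog <- cell_type_catalog(c(old_catalog$known, new_types),
                                   unknown_label = old_catalog$unknown_label)

  if (length(new_types)) {
    L <- length(model$weights)
    out <- model$weights[[L]]
    fan_in <- nrow(out$W)
    limit <- sqrt(6 / fan_in)
    fresh <- with_seed(init_seed, {
      matrix(runif(fan_in * length(new_types), -limit, limit),
             nrow = fan_in)
    })
    # old columns map by class name; Unknown stays terminal
    old_pos <- match(old_catalog$classes, new_catalog$classes)
    W2 <- matrix(0, fan_in, length(new_catalog$classes))
    b2 <- rep(0, length(new_catalog$classes))
    W2[, old_pos] <- out$W
    b2[old_pos] <- out$b
    W2[, match(new_types, new_catalog$classes)] <- fresh
    model$weights[[L]] <- list(W = W2, b = b2)
    model$catalog <- new_catalog
  }
  model <- continual_fit(model, x, labels, config, policy, class_weights,
                         frozen_layers = if (length(new_types)) 1L
                                         else integer(0))
  model$version <- bump_version(model$version)
  model
}
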