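#' Training hyper-parameters
#'
#' Defaults mirror the published training regime: stochastic gradient
#' descent on mini-batches of 1024 profiles, 20% of the training data set
#' aside for validation, and early stopping on validation loss. The
#' optimizer's learning rate and momentum are exposed because no single
#' value suits every catalog size; the defaults (0.01, 0.9) are the
#' conventional SGD settings for small fully connected networks.
#'
#' @param batch_size Mini-batch size (default 1024).
#' @param validation_fraction Fraction of training cells held out for
#'   validation (default 0.2), split stratified by class.
#' @param max_epochs Upper bound on training epochs (default 50).
#' @param patience Epochs without validation-loss improvement before
#'   stopping; best-epoch weights are restored (default 3).
#' @param learning_rate,momentum SGD settings.
#' @param seed Integer seed controlling the split, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 1024L, validation_fraction = 0.2,
                         max_epochs = 50L, patience = 3L,
                         learning_rate = 0.01, momentum = 0.9, seed = NULL) {
  stopifnot(batch_size >= 1L, validation_fraction > 0, validation_fraction < 1,
            max_epochs >= 0L, patience >= 1L, learning_rate > 0,
            momentum >= 0, momentum < 1)
  structure(list(batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 momentum = momentum,
                 seed = seed),
            class = "train_config")
}

#' Initialize a cell-type classifier network
#'
#' Builds the fully connected architecture: one input node per gene-space
#' symbol, hidden dense layers of 200 and 100 rectified-linear units by
#' default, dropout after each hidden layer, and one softmax output node
#' per catalog class (K known types + Unknown). Weights use scaled-uniform
#' fan-in initialization, \eqn{U(-\sqrt{6/n_{in}}, \sqrt{6/n_{in}})};
#' biases start at zero. The same seed yields bit-identical weights.
#'
#' @param catalog A [cell_type_catalog()].
#' @param gs A [gene_space()] defining the input nodes.
#' @param hidden_sizes Integer vector of hidden-layer widths (default
#'   `c(200, 100)`).
#' @param dropout_rate Dropout probability applied after each hidden layer
#'   during training (default 0.4).
#' @param seed Integer seed for the weight draw.
#' @param version Version tag stored with the model (default `"v1"`).
#' @return An object of class `scident_model`.
#' @export
init_model <- function(catalog, gs, hidden_sizes = c(200L, 100L),
                       dropout_rate = 0.4, seed = NULL, version = "v1") {
  gs <- gene_space(gs)
  stopifnot(inherits(catalog, "cell_type_catalog"),
            all(hidden_sizes >= 1L), dropout_rate >= 0, dropout_rate < 1)
  sizes <- c(length(gs), as.integer(hidden_sizes), length(catalog$classes))
  weights <- with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      limit <- sqrt(6 / fan_in)
      list(W = matrix(runif(fan_in * sizes[l + 1L], -limit, limit),
                      nrow = fan_in, ncol = sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
  structure(
    list(config = list(input_size = length(gs),
                       hidden_sizes = as.integer(hidden_sizes),
                       dropout_rate = dropout_rate,
                       activation = "relu"),
         weights = weights,
         catalog = catalog,
         gene_space = gs,
         gene_space_hash = gene_space_hash(gs),
         version = version,
         history = NULL,
         replay = NULL),
    class = "scident_model"
  )
}

#' @export
print.scident_model <- function(x, ...) {
  cat(sprintf(
    "<scident_model %s> %d genes -> %s -> %d classes (%d known + '%s')\n",
    x$version, x$config$input_size,
    paste(x$config$hidden_sizes, collapse = " -> "),
    length(x$catalog$classes), length(x$catalog$known),
    x$catalog$unknown_label))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epoch(s); final val_loss %.4f\n",
                nrow(x$history), x$history$val_loss[nrow(x$history)]))
  }
  if (!is.null(x$replay)) {
    cat(sprintf("  replay pool: %d cells\n", nrow(x$replay$x)))
  }
  invisible(x)
}

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. Returns list(activations = list of post-activation matrices
# per layer incl. input, probs). With training = TRUE, applies inverted
# dropout after each hidden layer using masks drawn from the current RNG.
forward_pass <- function(weights, X, dropout_rate = 0, training = FALSE) {
  L <- length(weights)
  acts <- vector("list", L + 1L)
  masks <- vector("list", L)
  acts[[1L]] <- X
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% weights[[l]]$W, 2L, weights[[l]]$b, "+")
    if (l < L) {
      A <- relu(Z)
      if (training && dropout_rate > 0) {
        mask <- matrix(runif(length(A)) >= dropout_rate,
                       nrow = nrow(A)) / (1 - dropout_rate)
        A <- A * mask
        masks[[l]] <- mask
      }
    } else {
      A <- softmax_rows(Z)
    }
    acts[[l + 1L]] <- A
  }
  list(activations = acts, masks = masks, probs = A)
}

# Class-weighted categorical cross-entropy (natural log, mean over samples).
weighted_ce <- function(probs, y_idx, w) {
  p <- probs[cbind(seq_along(y_idx), y_idx)]
  mean(w * -log(pmax(p, 1e-12)))
}

# One SGD mini-batch update with momentum. `state` is an environment holding
# $weights and $velocity; frozen layer indices are skipped.
sgd_batch <- function(state, X, y_idx, w, lr, momentum, dropout_rate, frozen) {
  fw <- forward_pass(state$weights, X, dropout_rate, training = TRUE)
  L <- length(state$weights)
  n <- nrow(X)
  Y <- matrix(0, n, ncol(fw$probs))
  Y[cbind(seq_len(n), y_idx)] <- 1
  # softmax + CE gradient, per-sample class weights folded in
  delta <- (fw$probs - Y) * (w / n)
  for (l in rev(seq_len(L))) {
    A_prev <- fw$activations[[l]]
    if (!(l %in% frozen)) {
      gW <- crossprod(A_prev, delta)
      gb <- colSums(delta)
      state$velocity[[l]]$W <- momentum * state$velocity[[l]]$W - lr * gW
      state$velocity[[l]]$b <- momentum * state$velocity[[l]]$b - lr * gb
      state$weights[[l]]$W <- state$weights[[l]]$W + state$velocity[[l]]$W
      state$weights[[l]]$b <- state$weights[[l]]$b + state$velocity[[l]]$b
    }
    if (l > 1L) {
      delta <- delta %*% t(state$weights[[l]]$W)
      if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
      delta <- delta * (fw$activations[[l]] > 0)
    }
  }
  invisible(state)
}

# One full epoch over (X, y_idx): shuffle, then mini-batches.
sgd_epoch <- function(state, X, y_idx, w, cfg, frozen) {
  n <- nrow(X)
  ord <- sample.int(n)
  starts <- seq(1L, n, by = cfg$batch_size)
  for (s in starts) {
    idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
    sgd_batch(state, X[idx, , drop = FALSE], y_idx[idx], w[idx],
              cfg$learning_rate, cfg$momentum,
              state$dropout_rate, frozen)
  }
  invisible(state)
}

eval_split <- function(weights, X, y_idx, w = rep(1, length(y_idx))) {
  fw <- forward_pass(weights, X)
  pred <- max.col(fw$probs, ties.method = "first")
  list(loss = weighted_ce(fw$probs, y_idx, w),
       accuracy = mean(pred == y_idx))
}

# Stratified index split: per class, about `frac` of cells go to validation;
# classes too small to spare a cell stay entirely in training.
stratified_split <- function(y_idx, frac) {
  val <- integer(0)
  for (cls in unique(y_idx)) {
    members <- which(y_idx == cls)
    n_val <- floor(length(members) * frac)
    if (n_val >= 1L && n_val < length(members)) {
      val <- c(val, sample(members, n_val))
    }
  }
  sort(val)
}

validate_binary_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(x) && !all(x == 0 | x == 1)) {
    stopf("profile matrix must be strictly binary (0/1); run binarize() first")
  }
  x
}

check_gene_space_match <- function(model, x) {
  if (ncol(x) != model$config$input_size) {
    stopf("input has %d gene columns but the model expects %d",
          ncol(x), model$config$input_size)
  }
  if (!is.null(colnames(x)) &&
      gene_space_hash(gene_space(colnames(x))) != model$gene_space_hash) {
    warnf("input gene columns do not hash to the model's gene space; did you align_to_gene_space()?")
  }
}

#' Train the classifier
#'
#' Minimizes class-weighted categorical cross-entropy by SGD with momentum
#' over mini-batches, holding out a stratified validation split and stopping
#' early when validation loss stops improving (best-epoch weights are
#' restored). Dropout is active during training only. The training data and
#' labels are retained on the returned model as the replay pool for later
#' review training (see [online_update()]).
#'
#' @param model An [init_model()] classifier (or one to continue training).
#' @param x Cells-by-genes binary matrix aligned to the model's gene space.
#' @param labels Character vector of catalog labels, one per row of `x`.
#' @param config A [train_config()].
#' @param class_weights A tibble from [compute_class_weights()], or `NULL`
#'   for unweighted training.
#' @param frozen_layers Integer indices of layers excluded from updates
#'   (1 = first hidden layer); used by catalog expansion.
#' @param keep_replay Retain `(x, labels)` on the model as the replay pool
#'   (default `TRUE`).
#' @return The trained `scident_model`, with a `$history` tibble of
#'   per-epoch training/validation loss and accuracy.
#' @export
train_classifier <- function(model, x, labels, config = train_config(),
                             class_weights = NULL, frozen_layers = integer(0),
                             keep_replay = TRUE) {
  stopifnot(inherits(model, "scident_model"), inherits(config, "train_config"))
  x <- validate_binary_matrix(x)
  labels <- as_label_vector(labels, rownames(x))
  if (nrow(x) != length(labels)) stopf("rows of x and labels differ in length")
  check_gene_space_match(model, x)
  y_idx <- catalog_index(labels, model$catalog)
  if (length(unique(y_idx)) < 2L) {
    stopf("training labels contain a single class; nothing to discriminate")
  }
  w_all <- sample_weights(labels, class_weights)

  hist <- NULL
  state <- new.env(parent = emptyenv())
  state$weights <- model$weights
  state$velocity <- lapply(model$weights, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  state$dropout_rate <- model$config$dropout_rate

  with_seed(config$seed, {
    val_idx <- stratified_split(y_idx, config$validation_fraction)
    tr_idx <- setdiff(seq_len(nrow(x)), val_idx)
    if (!all(unique(y_idx) %in% y_idx[tr_idx])) {
      stopf("a class is absent from the training split; more cells needed")
    }
    Xt <- x[tr_idx, , drop = FALSE]; yt <- y_idx[tr_idx]; wt <- w_all[tr_idx]
    Xv <- x[val_idx, , drop = FALSE]; yv <- y_idx[val_idx]

    best <- list(loss = Inf, weights = state$weights, epoch = 0L)
    stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      sgd_epoch(state, Xt, yt, wt, config, frozen_layers)
      tr <- eval_split(state$weights, Xt, yt, wt)
      va <- if (length(val_idx)) eval_split(state$weights, Xv, yv) else tr
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     loss = tr$loss, accuracy = tr$accuracy,
                                     val_loss = va$loss,
                                     val_accuracy = va$accuracy))
      if (va$loss < best$loss - 1e-9) {
        best <- list(loss = va$loss, weights = state$weights, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    if (best$epoch > 0L) state$weights <- best$weights
  })

  model$weights <- state$weights
  model$history <- if (is.null(hist)) {
    tibble::tibble(epoch = integer(), loss = double(), accuracy = double(),
                   val_loss = double(), val_accuracy = double())
  } else {
    tibble::as_tibble(hist)
  }
  if (keep_replay) model$replay <- list(x = x, labels = labels)
  model
}

#' Predict cell types
#'
#' Runs the forward pass (dropout disabled) and assigns each cell the
#' catalog class with the highest softmax probability; ties break to the
#' lowest catalog index. Prediction is deterministic: the same profile
#' always receives the same label.
#'
#' @param object A trained `scident_model`.
#' @param x Cells-by-genes binary matrix aligned to the model's gene space.
#' @param type `"tibble"` (default) for a per-cell table with one
#'   probability column per class, `"label"` for the label vector,
#'   `"prob"` for the raw probability matrix.
#' @param ... Unused.
#' @return See `type`. The tibble has columns `cell_id`, `predicted_type`,
#'   `max_probability`, then one column per catalog class.
#' @export
predict.scident_model <- function(object, x, type = c("tibble", "label", "prob"),
                                  ...) {
  type <- match.arg(type)
  x <- validate_binary_matrix(x)
  check_gene_space_match(object, x)
  probs <- forward_pass(object$weights, x)$probs
  colnames(probs) <- object$catalog$classes
  pred_idx <- max.col(probs, ties.method = "first")
  labels <- object$catalog$classes[pred_idx]
  switch(type,
    label = labels,
    prob = probs,
    tibble = {
      ids <- rownames(x) %||% sprintf("cell_%d", seq_len(nrow(x)))
      dplyr::bind_cols(
        tibble::tibble(cell_id = ids,
                       predicted_type = labels,
                       max_probability = probs[cbind(seq_len(nrow(probs)),
                                                     pred_idx)]),
        tibble::as_tibble(probs)
      )
    })
}
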