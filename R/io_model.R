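#' Save / load a classifier model archive
#'
#' The archive is a single JSON file holding a manifest (architecture,
#' catalog, gene space + hash, version tag, training history) and the
#' weight tensors encoded as base64 little-endian IEEE-754 doubles, so
#' `load_model(save_model(m))` reproduces every weight bit-exactly. The
#' replay pool (binary profiles + labels used for review training) is
#' stored sparsely — only the indices of present genes per cell — and can
#' be omitted to keep archives small.
#'
#' @param model A `scident_model`.
#' @param path Target file.
#' @param include_replay Store the replay pool (default `TRUE`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the reconstructed `scident_model`.
#' @export
save_model <- function(model, path, include_replay = TRUE) {
  stopifnot(inherits(model, "scident_model"))
  enc <- function(v) jsonlite::base64_enc(writeBin(as.double(v), raw(),
                                                   size = 8L,
                                                   endian = "little"))
  manifest <- list(
    format = "scident_model",
    schema_version = 1L,
    version = model$version,
    config = model$config,
    catalog = list(known = model$catalog$known,
                   unknown_label = model$catalog$unknown_label),
    gene_space = unclass(model$gene_space),
    gene_space_hash = model$gene_space_hash,
    weights = lapply(model$weights, function(l) {
      list(dim = dim(l$W), W = enc(l$W), b = enc(l$b))
    }),
    history = if (is.null(model$history)) NULL else as.list(model$history)
  )
  if (include_replay && !is.null(model$replay)) {
    rp <- model$replay
    manifest$replay <- list(
      n = nrow(rp$x), p = ncol(rp$x),
      cell_ids = rownames(rp$x),
      present = apply(rp$x, 1L, function(r) which(r > 0), simplify = FALSE),
      labels = rp$labels
    )
  }
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  manifest <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stopf("not a readable model archive (%s): %s",
                              path, conditionMessage(e))
  )
  if (!identical(manifest$format, "scident_model")) {
    stopf("file is not a classifier model archive: %s", path)
  }
  if (!identical(as.integer(manifest$schema_version), 1L)) {
    stopf("unsupported model schema version: %s", manifest$schema_version)
  }
  dec <- function(b64, n) readBin(jsonlite::base64_dec(b64), "double",
                                  n = n, size = 8L, endian = "little")
  weights <- lapply(manifest$weights, function(l) {
    d <- as.integer(unlist(l$dim))
    list(W = matrix(dec(l$W, prod(d)), nrow = d[1L], ncol = d[2L]),
         b = dec(l$b, d[2L]))
  })
  gs <- gene_space(unlist(manifest$gene_space))
  if (!is.null(manifest$gene_space_hash) &&
      gene_space_hash(gs) != manifest$gene_space_hash) {
    warnf("stored gene-space hash does not match its symbol list")
  }
  model <- structure(
    list(config = list(
           input_size = as.integer(manifest$config$input_size),
           hidden_sizes = as.integer(unlist(manifest$config$hidden_sizes)),
           dropout_rate = manifest$config$dropout_rate,
           activation = manifest$config$activation),
         weights = weights,
         catalog = cell_type_catalog(unlist(manifest$catalog$known),
                                     manifest$catalog$unknown_label),
         gene_space = gs,
         gene_space_hash = gene_space_hash(gs),
         version = manifest$version,
         history = if (is.null(manifest$history) ||
                       length(manifest$history$epoch) == 0L) NULL else
           tibble::as_tibble(lapply(manifest$history, unlist)),
         replay = NULL),
    class = "scident_model"
  )
  if (!is.null(manifest$replay)) {
    rp <- manifest$replay
    x <- matrix(0, nrow = rp$n, ncol = rp$p,
                dimnames = list(unlist(rp$cell_ids), unclass(gs)))
    for (i in seq_len(rp$n)) {
      idx <- unlist(rp$present[[i]])
      if (length(idx)) x[i, idx] <- 1
    }
    model$replay <- list(x = x, labels = unlist(rp$labels))
  }
  model
}
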