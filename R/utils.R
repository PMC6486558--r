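# Internal helpers shared across modules.

# Gene symbols are matched case-insensitively and whitespace is ignored:
# human/mouse homolog pairs typically differ only in case (CD3D vs Cd3d).
normalize_symbols <- function(x) {
  toupper(gsub("[[:space:]]+", "", as.character(x)))
}

# Run `expr` under a locally-set RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Coerce a labels argument (character vector, factor, or a data frame with
# cell_id/label columns) to a plain character vector, optionally checked
# against the cell IDs of a companion matrix.
as_label_vector <- function(labels, cell_ids = NULL) {
  if (is.data.frame(labels)) {
    if (!all(c("cell_id", "label") %in% names(labels))) {
      stopf("label table must have columns 'cell_id' and 'label'")
    }
    if (!is.null(cell_ids)) {
      idx <- match(cell_ids, labels$cell_id)
      if (anyNA(idx)) {
        stopf("%d cell(s) in the matrix have no label", sum(is.na(idx)))
      }
      return(as.character(labels$label[idx]))
    }
    return(as.character(labels$label))
  }
  as.character(labels)
}
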