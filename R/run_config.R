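#' Run configuration for command-line workflows
#'
#' A flat, fully defaulted set of knobs covering the network architecture,
#' the SGD schedule and the review policy, serializable to YAML so a run
#' is reproducible from its config file plus a seed. Unknown keys are
#' rejected rather than ignored — a typo in a config should fail loudly.
#'
#' @param ... Overrides for the default fields: `hidden_sizes`,
#'   `dropout_rate`, `batch_size`, `validation_fraction`, `max_epochs`,
#'   `patience`, `learning_rate`, `momentum`, `review_size`, `seed`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    hidden_sizes = c(200L, 100L),
    dropout_rate = 0.4,
    batch_size = 1024L,
    validation_fraction = 0.2,
    max_epochs = 30L,
    patience = 3L,
    learning_rate = 0.01,
    momentum = 0.9,
    review_size = 4000L,
    seed = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to read or write.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, as.list(vals))
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   path)
  invisible(path)
}

as_train_config <- function(cfg, seed = NULL) {
  train_config(batch_size = cfg$batch_size,
               validation_fraction = cfg$validation_fraction,
               max_epochs = cfg$max_epochs,
               patience = cfg$patience,
               learning_rate = cfg$learning_rate,
               momentum = cfg$momentum,
               seed = seed %||% cfg$seed)
}
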