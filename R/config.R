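#' Experiment configuration files
#'
#' An experiment configuration bundles the model configuration, loss
#' weights, optimizer/schedule settings, split fractions and the master
#' seed, serialized as YAML. Unknown keys are rejected so typos fail loudly
#' rather than silently falling back to defaults. Load-dump-load is the
#' identity.
#'
#' @param model Named list of [bmt_config()] arguments.
#' @param weights Named list of [loss_weights()] arguments.
#' @param optimizer Named list: \code{epochs}, \code{lr}, \code{lr_decay},
#'   \code{lr_step}, \code{batch_size}, \code{patience}.
#' @param split Length-3 fractions (train, validation, test).
#' @param seed Master seed.
#' @return List of class \code{"experiment_config"}.
#' @export
experiment_config <- function(model = list(), weights = list(),
                              optimizer = list(), split = c(0.7, 0.1, 0.2),
                              seed = 1L) {
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_keys(model, c("b", "d", "d_K", "d_V", "d_H", "heads", "layers",
                      "dropout", "beta", "variant"), "model")
  check_keys(weights, c("alpha1", "alpha2", "alpha3", "alpha4"), "weights")
  check_keys(optimizer, c("epochs", "lr", "lr_decay", "lr_step",
                          "batch_size", "patience"), "optimizer")
  opt <- utils::modifyList(
    list(epochs = 30L, lr = 1e-4, lr_decay = 0.9, lr_step = 15L,
         batch_size = 16L, patience = 10L),
    optimizer
  )
  structure(list(model = model, weights = weights, optimizer = opt,
                 split = as.numeric(split), seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read configuration files",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  allowed <- c("model", "weights", "optimizer", "split", "seed")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(experiment_config, raw)
}

#' @rdname experiment_config
#' @param cfg An \code{experiment_config}.
#' @export
write_experiment_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to write configuration files",
         call. = FALSE)
  }
  writeLines(yaml::as.yaml(unclass(cfg)), path)
  invisible(path)
}

#' Build the training call from an experiment configuration
#'
#' @param config An [experiment_config()].
#' @param dataset An [event_dataset()].
#' @param variant Optional variant override.
#' @return A trained \code{"bmt_model"}.
#' @export
run_experiment <- function(config, dataset, variant = NULL) {
  margs <- config$model
  if (!is.null(variant)) margs$variant <- variant
  cfg <- do.call(bmt_config, margs)
  w <- do.call(loss_weights, config$weights)
  w <- variant_weights(cfg$variant, w)
  opt <- config$optimizer
  train_bmt(dataset, cfg, weights = w, epochs = opt$epochs, lr = opt$lr,
            lr_decay = opt$lr_decay, lr_step = opt$lr_step,
            batch_size = opt$batch_size, seed = config$seed,
            patience = opt$patience, split = config$split)
}
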