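# Parameter trees are nested lists of numeric leaves. The optimizer works
# on a flat vector; these helpers flatten/restore and align gradient trees
# to the parameter ordering.

flatten_tree <- function(x) {
  if (is.list(x)) unlist(lapply(x, flatten_tree), use.names = FALSE)
  else as.numeric(x)
}

unflatten_tree <- function(v, template) {
  pos <- 0L
  rec <- function(tpl) {
    if (is.list(tpl)) return(lapply(tpl, rec))
    k <- length(tpl)
    out <- v[(pos + 1L):(pos + k)]
    pos <<- pos + k
    if (is.matrix(tpl)) dim(out) <- dim(tpl)
    out
  }
  rec(template)
}

align_tree <- function(template, x) {
  if (!is.list(template)) return(x)
  nm <- names(template)
  if (is.null(nm)) {
    lapply(seq_along(template), function(i) align_tree(template[[i]], x[[i]]))
  } else {
    out <- lapply(nm, function(n) align_tree(template[[n]], x[[n]]))
    names(out) <- nm
    out
  }
}

#' Split a dataset into train/validation/test index sets
#'
#' @param n Number of sequences.
#' @param fractions Length-3 non-negative fractions summing to 1
#'   (train, validation, test).
#' @param seed Integer seed; the split is deterministic given it.
#' @return List of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
split_dataset <- function(n, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 non-negative values summing to 1", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- floor(fractions[1] * n)
  n_va <- floor(fractions[2] * n)
  list(train = sort(perm[seq_len(n_tr)]),
       val = sort(perm[n_tr + seq_len(n_va)]),
       test = sort(perm[(n_tr + n_va + 1L):n]))
}

#' Train the burst- and memory-aware transformer
#'
#' ADAM optimization (betas 0.9/0.999) of the weighted five-part objective
#' with step learning-rate decay, mini-batches of sequences, dropout, and
#' early stopping on the validation total loss. Gradients are the mean of
#' per-sequence gradients over the batch. Deterministic under \code{seed}:
#' the seed drives the split, the parameter initialization, the shuffling
#' and the dropout masks.
#'
#' @param dataset An [event_dataset()].
#' @param cfg A [bmt_config()].
#' @param weights Loss weights; default [variant_weights()] of the config's
#'   variant applied to the full-scale defaults.
#' @param epochs Maximum number of epochs.
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor.
#' @param lr_step Epochs between decays.
#' @param batch_size Sequences per gradient step.
#' @param seed Master seed.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); \code{Inf} disables.
#' @param split Train/validation/test fractions.
#' @param verbose Print per-epoch losses.
#' @return List of class \code{"bmt_model"}: \code{params} (best by
#'   validation loss), \code{cfg}, \code{weights}, \code{history} (per-epoch
#'   data frame), \code{split} (index sets), \code{seed}.
#' @export
train_bmt <- function(dataset, cfg, weights = NULL, epochs = 30L, lr = 1e-4,
                      lr_decay = 0.9, lr_step = 15L, batch_size = 16L,
                      seed = 1L, patience = 10L, split = c(0.7, 0.1, 0.2),
                      verbose = FALSE) {
  if (is.null(weights)) weights <- variant_weights(cfg$variant)
  check_variant_weights(cfg$variant, weights)
  n_seq <- length(dataset)
  if (n_seq < 3L) stop("need at least 3 sequences", call. = FALSE)
  prep <- lapply(dataset, prepare_sequence, cfg = cfg)
  idx <- split_dataset(n_seq, split, seed = seed)
  params <- bmt_init_params(cfg, seed = seed + 7919L)
  set.seed(seed + 104729L)

  theta <- flatten_tree(params)
  m_t <- numeric(length(theta))
  v_t <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  best_val <- Inf
  best_theta <- theta
  stall <- 0L
  hist <- vector("list", epochs)

  val_loss <- function(par) {
    tot <- 0
    for (i in idx$val) {
      fwd <- bmt_forward(par, cfg, prep[[i]], training = FALSE)
      tot <- tot + loss_bundle(fwd$loss, weights, cfg$variant)$total
    }
    tot / max(length(idx$val), 1L)
  }

  for (epoch in seq_len(epochs)) {
    lr_e <- lr * lr_decay^((epoch - 1L) %/% lr_step)
    ord <- sample(idx$train)
    comp <- c(L_t = 0, L_lambda = 0, L_BM = 0, L_B = 0, L_M = 0, total = 0)
    n_bm <- 0L
    for (start in seq(1L, length(ord), by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, length(ord))]
      gsum <- numeric(length(theta))
      for (i in batch) {
        fwd <- bmt_forward(params, cfg, prep[[i]], training = TRUE,
                           keep_cache = TRUE)
        bk <- bmt_backward(params, cfg, prep[[i]], fwd, weights)
        gsum <- gsum + flatten_tree(align_tree(params, bk$grads))
        bb <- bk$bundle
        comp["L_t"] <- comp["L_t"] + bb$L_t
        comp["L_lambda"] <- comp["L_lambda"] + bb$L_lambda
        if (!is.na(bb$L_BM)) {
          comp["L_BM"] <- comp["L_BM"] + bb$L_BM
          n_bm <- n_bm + 1L
        }
        comp["L_B"] <- comp["L_B"] + bb$L_B
        comp["L_M"] <- comp["L_M"] + bb$L_M
        comp["total"] <- comp["total"] + bb$total
      }
      gbar <- gsum / length(batch)
      if (any(!is.finite(gbar))) {
        stop(sprintf("divergence: non-finite gradient at epoch %d", epoch),
             call. = FALSE)
      }
      step <- step + 1L
      m_t <- b1 * m_t + (1 - b1) * gbar
      v_t <- b2 * v_t + (1 - b2) * gbar^2
      theta <- theta - lr_e * (m_t / (1 - b1^step)) /
        (sqrt(v_t / (1 - b2^step)) + eps)
      params <- unflatten_tree(theta, params)
    }
    ntr <- length(idx$train)
    vl <- val_loss(params)
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr_e,
      train_L_t = comp[["L_t"]] / ntr,
      train_L_lambda = comp[["L_lambda"]] / ntr,
      train_L_BM = if (n_bm > 0) comp[["L_BM"]] / n_bm else NA_real_,
      train_L_B = comp[["L_B"]] / ntr,
      train_L_M = comp[["L_M"]] / ntr,
      train_total = comp[["total"]] / ntr,
      val_total = vl
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.4g  val %.4g  lr %.2g",
                      epoch, comp[["total"]] / ntr, vl, lr_e))
    }
    if (vl < best_val - 1e-12) {
      best_val <- vl
      best_theta <- theta
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  structure(
    list(params = unflatten_tree(best_theta, params), cfg = cfg,
         weights = weights, history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
         split = idx, seed = seed, best_val = best_val),
    class = "bmt_model"
  )
}

#' @export
print.bmt_model <- function(x, ...) {
  cat(sprintf("<bmt_model> variant %s, %d layer(s), d = %d, %d epoch(s) trained\n",
              x$cfg$variant, x$cfg$layers, x$cfg$d,
              if (is.null(x$history)) 0L else nrow(x$history)))
  invisible(x)
}

#' Evaluate a trained model
#'
#' Event-time RMSE is the square root of the mean squared error pooled
#' over all predicted events of all sequences (unit-adjusted, comparable
#' across datasets). The log-likelihood and token cross-entropy are
#' reported per event; cross-entropy is \code{NA} for variants without the
#' token head.
#'
#' @param model A [train_bmt()] result.
#' @param dataset Held-out [event_dataset()].
#' @return List of class \code{"bmt_eval"} with \code{rmse_time},
#'   \code{ll_per_event}, \code{ce_bm_per_event}, \code{n_sequences},
#'   \code{n_events}.
#' @export
evaluate_bmt <- function(model, dataset) {
  if (!length(dataset)) stop("empty evaluation dataset", call. = FALSE)
  cfg <- model$cfg
  sse <- 0; n_pred <- 0L
  ll <- 0; n_ev <- 0L
  ce <- 0; n_ce <- 0L
  for (seq in dataset) {
    sd <- prepare_sequence(seq, cfg)
    fwd <- bmt_forward(model$params, cfg, sd, training = FALSE)
    k <- sd$n - 1L
    sse <- sse + sum((sd$times[-1L] - fwd$that[seq_len(k)])^2)
    n_pred <- n_pred + k
    ll <- ll + fwd$loss$LL
    n_ev <- n_ev + k
    if (cfg$has_token_head && fwd$n_ce > 0) {
      ce <- ce + fwd$loss$L_BM
      n_ce <- n_ce + fwd$n_ce
    }
  }
  structure(
    list(rmse_time = sqrt(sse / n_pred),
         ll_per_event = ll / n_ev,
         ce_bm_per_event = if (cfg$has_token_head && n_ce > 0) ce / n_ce else NA_real_,
         n_sequences = length(dataset), n_events = n_pred),
    class = "bmt_eval"
  )
}

#' @export
print.bmt_eval <- function(x, ...) {
  cat(sprintf(
    "<bmt_eval> %d sequences / %d events: RMSE %.4g, LL/event %.4g, CE/event %s\n",
    x$n_sequences, x$n_events, x$rmse_time, x$ll_per_event,
    if (is.na(x$ce_bm_per_event)) "N/A" else sprintf("%.4g", x$ce_bm_per_event)
  ))
  invisible(x)
}

#' Run the ablation suite
#'
#' Trains the requested variants on one dataset with shared splits and
#' shared per-run seeds, evaluates each on the held-out test set, and
#' returns both the raw per-run results and a summary shaped like the
#' standard comparison table (median across seeds per variant; "N/A" where
#' the variant has no token cross-entropy head). Per-variant failures are
#' caught and reported as \code{NA} rows.
#'
#' @param dataset An [event_dataset()].
#' @param variants Character vector of variant names.
#' @param seeds Integer vector of seeds, or a named list mapping variant
#'   name to its seed vector (unnamed variants fall back to the first
#'   seed).
#' @param cfg_fn Function \code{variant -> bmt_config}; default
#'   [reduced_config()].
#' @param ... Passed to [train_bmt()] (epochs, lr, batch_size, ...).
#' @return List with \code{runs} (data frame: variant, seed, rmse_time,
#'   ll_per_event, ce_bm_per_event) and \code{table} (data frame: variant,
#'   rmse_time, ll, ce_bm as character with "N/A").
#' @export
run_ablation_suite <- function(dataset,
                               variants = c("NoE&NoL", "NoE&L", "E&NoL",
                                            "B", "M", "BMT"),
                               seeds = c(1L, 2L, 3L),
                               cfg_fn = reduced_config, ...) {
  seed_for <- function(v) {
    if (is.list(seeds)) {
      if (!is.null(seeds[[v]])) seeds[[v]] else seeds[[1L]][1L]
    } else {
      seeds
    }
  }
  rows <- list()
  for (v in variants) {
    cfg <- cfg_fn(variant = v)
    for (s in seed_for(v)) {
      res <- tryCatch({
        mdl <- train_bmt(dataset, cfg, seed = s, ...)
        ev <- evaluate_bmt(mdl, dataset[mdl$split$test])
        data.frame(variant = v, seed = s, rmse_time = ev$rmse_time,
                   ll_per_event = ev$ll_per_event,
                   ce_bm_per_event = ev$ce_bm_per_event,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("variant %s seed %d failed: %s", v, s,
                        conditionMessage(e)), call. = FALSE)
        data.frame(variant = v, seed = s, rmse_time = NA_real_,
                   ll_per_event = NA_real_, ce_bm_per_event = NA_real_,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  runs <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(variants, function(v) {
    r <- runs[runs$variant == v, ]
    ce <- stats::median(r$ce_bm_per_event)
    data.frame(
      variant = v,
      rmse_time = stats::median(r$rmse_time),
      ll = stats::median(r$ll_per_event),
      ce_bm = if (is.na(ce)) "N/A" else sprintf("%.3f", ce),
      n_runs = nrow(r),
      stringsAsFactors = FALSE
    )
  }))
  list(runs = runs, table = tab)
}

#' Save / load model checkpoints
#'
#' The checkpoint stores configuration, parameters, loss weights, training
#' history and the RNG state, so training diagnostics and evaluation are
#' reproducible after a reload. The configuration is additionally written
#' as a YAML sidecar (\code{<path>.yaml}) when the \pkg{yaml} package is
#' available.
#'
#' @param model A [train_bmt()] result.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  obj <- list(cfg = unclass(model$cfg), params = model$params,
              weights = unclass(model$weights), history = model$history,
              split = model$split, seed = model$seed, rng_state = rng)
  saveRDS(obj, path)
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg_flat <- model$cfg[c("b", "d", "d_K", "d_V", "d_H", "heads", "layers",
                            "dropout", "beta", "variant")]
    writeLines(yaml::as.yaml(cfg_flat), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @return \code{load_checkpoint}: the restored \code{"bmt_model"}.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(bmt_config, obj$cfg[c("b", "d", "d_K", "d_V", "d_H", "heads",
                                       "layers", "dropout", "beta", "variant")])
  if (!is.null(obj$rng_state)) {
    assign(".Random.seed", obj$rng_state, envir = globalenv())
  }
  structure(
    list(params = obj$params, cfg = cfg,
         weights = structure(obj$weights, class = "loss_weights"),
         history = obj$history, split = obj$split, seed = obj$seed),
    class = "bmt_model"
  )
}
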