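# Shared helpers: tiny deterministic objects built in code.

tiny_sequence <- function(n = 12L, seed = 5L) {
  generate_copula_sequence(copula_spec(
    "power_law", n_events = n, alpha = 2.5, memory_target = 0.2, seed = seed
  ))
}

tiny_config <- function(variant = "BMT", ...) {
  args <- utils::modifyList(
    list(b = 3L, d = 8L, d_K = 4L, d_V = 8L, d_H = 10L, heads = 2L,
         layers = 2L, dropout = 0, variant = variant),
    list(...)
  )
  do.call(bmt_config, args)
}

# central finite difference of the weighted total loss wrt one flat coord
numeric_grad <- function(params, cfg, sd, w, coords, eps = 1e-5) {
  th <- bmtpp:::flatten_tree(params)
  f <- function(v) {
    p <- bmtpp:::unflatten_tree(v, params)
    loss_bundle(bmt_forward(p, cfg, sd)$loss, w, cfg$variant)$total
  }
  vapply(coords, function(j) {
    tp <- th; tp[j] <- tp[j] + eps
    tm <- th; tm[j] <- tm[j] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
}

analytic_grad_flat <- function(params, cfg, sd, w) {
  fwd <- bmt_forward(params, cfg, sd, keep_cache = TRUE)
  bk <- bmt_backward(params, cfg, sd, fwd, w)
  bmtpp:::flatten_tree(bmtpp:::align_tree(params, bk$grads))
}
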