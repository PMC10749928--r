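#' Model configuration
#'
#' Hyperparameters of the burst- and memory-aware transformer. The defaults
#' are the full-scale settings (40 bins, embedding width 128, 8 layers and
#' 8 heads); [reduced_config()] gives a desk-scale profile.
#'
#' The \code{variant} selects the ablation arm:
#' \describe{
#'   \item{BMT}{joint B&M token embedding, all losses active.}
#'   \item{NoE&NoL}{no token embedding, no B/M losses — the plain
#'     transformer point-process control.}
#'   \item{NoE&L}{no token embedding but B and M value losses active.}
#'   \item{E&NoL}{token embedding on, B/M losses off (the token
#'     cross-entropy head still exists and is reported, just untrained).}
#'   \item{B}{B-only embedding (vocabulary \code{b}) and B value loss.}
#'   \item{M}{M-only embedding and M value loss.}
#' }
#'
#' @param b Bins per coefficient for tokenization.
#' @param d Embedding/model width (even).
#' @param d_K Per-head query/key width.
#' @param d_V Total value width across heads (divisible by \code{heads}).
#' @param d_H Feed-forward hidden width.
#' @param heads Number of attention heads.
#' @param layers Number of encoder layers.
#' @param dropout Dropout rate applied to sublayer outputs during training.
#' @param beta Softplus softness of the intensity head.
#' @param variant Ablation variant, see Details.
#' @return List of class \code{"bmt_config"} with derived fields
#'   \code{embed_mode} (\code{"BM"}, \code{"B"}, \code{"M"} or
#'   \code{"none"}), \code{vocab_size}, and \code{has_token_head}.
#' @export
bmt_config <- function(b = 40L, d = 128L, d_K = 32L, d_V = 32L, d_H = 128L,
                       heads = 8L, layers = 8L, dropout = 0.1, beta = 1,
                       variant = c("BMT", "NoE&NoL", "NoE&L", "E&NoL",
                                   "B", "M")) {
  variant <- match.arg(variant)
  d <- as.integer(d)
  if (d %% 2L != 0L) stop("d must be even", call. = FALSE)
  if (as.integer(d_V) %% as.integer(heads) != 0L) {
    stop("d_V must be divisible by heads", call. = FALSE)
  }
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  embed_mode <- switch(variant,
    "BMT" = "BM", "E&NoL" = "BM", "B" = "B", "M" = "M",
    "NoE&NoL" = "none", "NoE&L" = "none"
  )
  vocab <- if (embed_mode == "none") 0L else bm_vocab_size(b, embed_mode)
  structure(
    list(b = as.integer(b), d = d, d_K = as.integer(d_K),
         d_V = as.integer(d_V), d_H = as.integer(d_H),
         heads = as.integer(heads), layers = as.integer(layers),
         dropout = dropout, beta = beta, variant = variant,
         embed_mode = embed_mode, vocab_size = vocab,
         has_token_head = identical(embed_mode, "BM")),
    class = "bmt_config"
  )
}

#' Desk-scale model configuration
#'
#' A small profile (2 layers, width 32, 2 heads, 8 bins) used for fast
#' experiments and the ablation harness; same architecture, smaller
#' everything.
#'
#' @inheritParams bmt_config
#' @param ... Overrides passed to [bmt_config()].
#' @export
reduced_config <- function(variant = "BMT", ...) {
  args <- utils::modifyList(
    list(b = 8L, d = 32L, d_K = 16L, d_V = 16L, d_H = 32L,
         heads = 2L, layers = 2L, dropout = 0.1, variant = variant),
    list(...)
  )
  do.call(bmt_config, args)
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize trainable parameters
#'
#' Glorot-uniform weight matrices, zero biases, unit layer-norm gains, and
#' a forget-gate bias of 1 for the LSTM. Deterministic under \code{seed}.
#'
#' @param cfg A [bmt_config()].
#' @param seed Integer seed.
#' @return Nested list of parameter matrices/vectors.
#' @export
bmt_init_params <- function(cfg, seed = 1L) {
  set.seed(seed)
  d <- cfg$d; dk <- cfg$d_K; dv <- cfg$d_V; dh <- cfg$d_H; m <- cfg$heads
  p <- list()
  if (cfg$embed_mode != "none") {
    # +1 column: reserved padding embedding for masked prefix entries
    p$W_E <- glorot(d, cfg$vocab_size + 1L)
  }
  p$layers <- lapply(seq_len(cfg$layers), function(l) {
    list(
      Wq = glorot(d, m * dk), Wk = glorot(d, m * dk), Wv = glorot(d, dv),
      Wo = glorot(dv, d),
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      W1 = glorot(d, dh), bf1 = rep(0, dh),
      W2 = glorot(dh, d), bf2 = rep(0, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d)
    )
  })
  p$lstm <- list(
    Wx = glorot(d, 4L * d), Wh = glorot(d, 4L * d),
    bl = c(rep(0, d), rep(1, d), rep(0, d), rep(0, d))  # forget bias 1
  )
  p$W_t <- as.numeric(glorot(d, 1L))
  p$w_lam <- as.numeric(glorot(d, 1L))
  if (cfg$has_token_head) p$W_BM <- glorot(d, cfg$vocab_size)
  p$w_B <- as.numeric(glorot(d, 1L))
  p$w_M <- as.numeric(glorot(d, 1L))
  p
}

#' Prepare a sequence for the model
#'
#' Precomputes everything the forward pass needs: timestamps, inter-event
#' times, the causal prefix burstiness/memory series, its validity mask,
#' and (for embedding variants) the dense token indices with masked entries
#' mapped to the padding index.
#'
#' @param seq An [event_sequence()].
#' @param cfg A [bmt_config()].
#' @return List with elements \code{times}, \code{iets}, \code{n},
#'   \code{B}, \code{M}, \code{valid}, \code{tokens} (NULL for
#'   no-embedding variants).
#' @export
prepare_sequence <- function(seq, cfg) {
  ts <- seq$timestamps
  bm <- prefix_bm_series(seq)
  tokens <- NULL
  if (cfg$embed_mode != "none") {
    tokens <- tokenize_bm(bm, cfg$b, cfg$embed_mode)
  }
  list(times = ts, iets = diff(ts), n = length(ts),
       B = bm$B, M = bm$M, valid = bm$valid, tokens = tokens)
}

layer_norm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat * 1, 2, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Forward pass of the model
#'
#' Runs embedding, the causally masked multi-head self-attention encoder
#' with position-wise feed-forward sublayers (post-norm residuals), the
#' unidirectional LSTM refinement, and the four predictor heads, and
#' assembles the unweighted loss components.
#'
#' @param params Parameters from [bmt_init_params()].
#' @param cfg A [bmt_config()].
#' @param sd Prepared sequence from [prepare_sequence()].
#' @param training Logical; enables dropout (fresh masks drawn from the
#'   active RNG stream).
#' @param keep_cache Logical; retain intermediates for [bmt_backward()].
#' @return List with \code{H} (n x d hidden rows), \code{that} (predicted
#'   next times, entry i predicts t_{i+1}), \code{lambda} (per-interval
#'   intensities, length n-1), \code{probs} (token distributions or NULL),
#'   \code{Bhat}, \code{Mhat}, \code{loss} (unweighted components
#'   \code{L_t}, \code{LL}, \code{L_BM}, \code{L_B}, \code{L_M}), and, if
#'   requested, \code{cache}.
#' @export
bmt_forward <- function(params, cfg, sd, training = FALSE, keep_cache = FALSE) {
  n <- sd$n
  d <- cfg$d; dk <- cfg$d_K; dv <- cfg$d_V; m <- cfg$heads
  dvh <- dv %/% m
  Zt <- positional_encoding(sd$times, d)
  if (cfg$embed_mode != "none") {
    Ze <- t(params$W_E[, sd$tokens + 1L, drop = FALSE])
    X <- Zt + Ze
  } else {
    X <- Zt
  }
  Z0 <- X
  cache <- if (keep_cache) list(layers = vector("list", cfg$layers)) else NULL

  neg_mask <- matrix(0, n, n)
  neg_mask[upper.tri(neg_mask)] <- -Inf

  for (l in seq_len(cfg$layers)) {
    lp <- params$layers[[l]]
    X_in <- X
    S <- matrix(0, n, dv)
    lcache <- if (keep_cache) list(heads = vector("list", m)) else NULL
    for (h in seq_len(m)) {
      iq <- ((h - 1L) * dk + 1L):(h * dk)
      iv <- ((h - 1L) * dvh + 1L):(h * dvh)
      Q <- X_in %*% lp$Wq[, iq, drop = FALSE]
      K <- X_in %*% lp$Wk[, iq, drop = FALSE]
      V <- X_in %*% lp$Wv[, iv, drop = FALSE]
      P <- softmax_rows(tcrossprod(Q, K) / sqrt(dk) + neg_mask)
      S[, iv] <- P %*% V
      if (keep_cache) lcache$heads[[h]] <- list(Q = Q, K = K, V = V, P = P)
    }
    SO <- S %*% lp$Wo
    drop1 <- NULL
    if (training && cfg$dropout > 0) {
      drop1 <- matrix(stats::rbinom(n * d, 1L, 1 - cfg$dropout), n, d) /
        (1 - cfg$dropout)
      SO <- SO * drop1
    }
    U1 <- X_in + SO
    ln1 <- layer_norm_fwd(U1, lp$ln1_g, lp$ln1_b)
    X1 <- ln1$y
    A <- X1 %*% lp$W1 + rep(lp$bf1, each = n)
    Rl <- A * (A > 0)
    Ff <- Rl %*% lp$W2 + rep(lp$bf2, each = n)
    drop2 <- NULL
    if (training && cfg$dropout > 0) {
      drop2 <- matrix(stats::rbinom(n * d, 1L, 1 - cfg$dropout), n, d) /
        (1 - cfg$dropout)
      Ff <- Ff * drop2
    }
    U2 <- X1 + Ff
    ln2 <- layer_norm_fwd(U2, lp$ln2_g, lp$ln2_b)
    X <- ln2$y
    if (keep_cache) {
      lcache$X_in <- X_in; lcache$S <- S; lcache$drop1 <- drop1
      lcache$ln1 <- ln1; lcache$X1 <- X1; lcache$A <- A; lcache$Rl <- Rl
      lcache$drop2 <- drop2; lcache$ln2 <- ln2
      cache$layers[[l]] <- lcache
    }
  }

  # unidirectional LSTM refinement
  lw <- params$lstm
  XWx <- X %*% lw$Wx
  Ig <- Fg <- Gg <- Og <- Cs <- Th <- H <- matrix(0, n, d)
  hprev <- numeric(d); cprev <- numeric(d)
  Hprev <- matrix(0, n, d)
  for (t in seq_len(n)) {
    Hprev[t, ] <- hprev
    a <- XWx[t, ] + as.numeric(hprev %*% lw$Wh) + lw$bl
    i_g <- stats::plogis(a[1:d])
    f_g <- stats::plogis(a[(d + 1):(2 * d)])
    g_g <- tanh(a[(2 * d + 1):(3 * d)])
    o_g <- stats::plogis(a[(3 * d + 1):(4 * d)])
    cprev <- f_g * cprev + i_g * g_g
    th <- tanh(cprev)
    hprev <- o_g * th
    Ig[t, ] <- i_g; Fg[t, ] <- f_g; Gg[t, ] <- g_g; Og[t, ] <- o_g
    Cs[t, ] <- cprev; Th[t, ] <- th; H[t, ] <- hprev
  }

  # heads ------------------------------------------------------------
  that <- as.numeric(H %*% params$W_t)        # that[i] predicts t_{i+1}
  lampre <- as.numeric(H %*% params$w_lam)
  zlam <- lampre[seq_len(n - 1L)] / cfg$beta - 1
  lambda <- cfg$beta * softplus(zlam)          # constant on [t_i, t_{i+1}]

  L_t <- sum((sd$times[-1L] - that[seq_len(n - 1L)])^2)
  LL <- sum(log(lambda)) - sum(lambda * sd$iets)

  probs <- NULL; L_BM <- NA_real_; ce_rows <- integer(0); ce_targets <- integer(0)
  if (cfg$has_token_head) {
    logits <- H[seq_len(n - 1L), , drop = FALSE] %*% params$W_BM
    probs <- softmax_rows(logits)
    tgt_pos <- which(sd$valid & seq_len(n) >= 2L)   # positions i with valid token
    ce_rows <- tgt_pos - 1L                          # predicted from h(t_{i-1})
    ce_targets <- sd$tokens[tgt_pos] + 1L
    pr <- pmax(probs[cbind(ce_rows, ce_targets)], 1e-12)
    L_BM <- -sum(log(pr))
  }

  bpre <- as.numeric(H %*% params$w_B)
  mpre <- as.numeric(H %*% params$w_M)
  Bhat <- tanh(bpre)
  Mhat <- tanh(mpre)
  val_pos <- which(sd$valid & seq_len(n) >= 2L)
  L_B <- sum((sd$B[val_pos] - Bhat[val_pos - 1L])^2)
  L_M <- sum((sd$M[val_pos] - Mhat[val_pos - 1L])^2)

  out <- list(
    H = H, that = that, lambda = lambda, probs = probs,
    Bhat = Bhat, Mhat = Mhat,
    loss = list(L_t = L_t, LL = LL, L_BM = L_BM, L_B = L_B, L_M = L_M),
    n_time = n - 1L, n_ce = length(ce_rows), n_val = length(val_pos)
  )
  if (any(!is.finite(H))) {
    stop("non-finite hidden state in forward pass", call. = FALSE)
  }
  if (keep_cache) {
    cache$Z0 <- Z0
    cache$lstm <- list(X = X, XWx = XWx, Ig = Ig, Fg = Fg, Gg = Gg, Og = Og,
                       Cs = Cs, Th = Th, Hprev = Hprev)
    cache$zlam <- zlam
    cache$bpre <- bpre; cache$mpre <- mpre
    cache$ce_rows <- ce_rows; cache$ce_targets <- ce_targets
    cache$val_pos <- val_pos
    out$cache <- cache
  }
  out
}

#' Piecewise-constant intensity of a fitted sequence
#'
#' Convenience accessor: intensities are constant on each inter-event
#' interval \code{[t_i, t_{i+1}]}, evaluated from the hidden state of the
#' preceding event, so the value "at" event \code{t_{i+1}} is the intensity
#' of the interval that ends there.
#'
#' @param fwd Output of [bmt_forward()].
#' @return Numeric vector of length n-1.
#' @export
interval_intensities <- function(fwd) fwd$lambda
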