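#' Discretize a value in [-1, 1] into b uniform bins
#'
#' Uniform partition of \code{[-1, 1]} into \code{b} half-open bins
#' \code{[edge_i, edge_{i+1})}, with the final bin closed so the right edge
#' 1 maps to bin \code{b}. Values outside \code{[-1, 1]} (possible only
#' through floating error upstream) are clamped with a warning.
#'
#' @param value Numeric vector of values in \code{[-1, 1]}.
#' @param b Number of bins, at least 2.
#' @return Integer bin indices in \code{1..b}.
#' @examples
#' discretize(c(0.2, -0.7, 1), b = 4)  # 3, 1, 4
#' @export
discretize <- function(value, b) {
  b <- as.integer(b)
  if (b < 2L) stop("b must be at least 2", call. = FALSE)
  if (any(value < -1 - 1e-9 | value > 1 + 1e-9, na.rm = TRUE)) {
    warning("values outside [-1, 1] clamped before discretization", call. = FALSE)
  }
  v <- pmin(pmax(value, -1), 1)
  idx <- floor((v + 1) / 2 * b) + 1L
  as.integer(pmin(idx, b))
}

#' Cantor pairing of two bin indices
#'
#' \eqn{d_{B,M} = \frac{1}{2}(d_B + d_M)(d_B + d_M + 1) + d_M}, an injective
#' map from ordered pairs of naturals to naturals used to fuse the
#' discretized burstiness and memory bins into a single token id. Order
#' matters: \code{cantor_pair(2, 1) != cantor_pair(1, 2)}.
#'
#' @param d_B,d_M Positive integer bin indices (vectorized).
#' @return Natural numbers.
#' @export
cantor_pair <- function(d_B, d_M) {
  if (any(d_B < 1) || any(d_M < 1)) stop("bin indices must be >= 1", call. = FALSE)
  s <- d_B + d_M
  s * (s + 1) / 2 + d_M
}

#' Vocabulary table for a b-by-b token grid
#'
#' Enumerates every \code{(d_B, d_M)} pair on the grid with its Cantor value
#' and its dense index: the rank of the Cantor value among all \code{b^2}
#' grid values, shifted to \code{0..b^2-1}. The Cantor image of the grid is
#' sparse (values reach past \code{b^2}); the dense rank makes the embedding
#' matrix and the one-hot dimension exactly \code{b^2} while preserving the
#' pairing's injectivity and order.
#'
#' @param b Number of bins per coefficient.
#' @return Data frame with columns \code{d_B}, \code{d_M}, \code{cantor},
#'   \code{dense} sorted by \code{dense}.
#' @export
bm_vocabulary <- function(b) {
  b <- as.integer(b)
  if (b < 2L) stop("b must be at least 2", call. = FALSE)
  grid <- expand.grid(d_B = seq_len(b), d_M = seq_len(b))
  grid$cantor <- cantor_pair(grid$d_B, grid$d_M)
  grid <- grid[order(grid$cantor), ]
  grid$dense <- seq_len(nrow(grid)) - 1L
  rownames(grid) <- NULL
  grid
}

#' Dense vocabulary index of a (d_B, d_M) pair
#'
#' @param d_B,d_M Bin indices in \code{1..b} (vectorized).
#' @param b Number of bins.
#' @return Integer dense indices in \code{0..b^2-1}.
#' @seealso [bm_vocabulary()] for the full table and the inverse mapping.
#' @export
dense_vocab_index <- function(d_B, d_M, b) {
  if (any(d_B < 1 | d_B > b) || any(d_M < 1 | d_M > b)) {
    stop("bin indices out of range 1..b", call. = FALSE)
  }
  vocab <- bm_vocabulary(b)
  key <- match(cantor_pair(d_B, d_M), vocab$cantor)
  vocab$dense[key]
}

#' Tokenize a prefix burstiness/memory series
#'
#' Maps each valid \code{(B_i, M_i)} entry of a [prefix_bm_series()] to its
#' dense token index; masked entries map to the reserved padding index
#' \code{vocab_size} (one past the last real token), which is excluded from
#' every loss. Single-coefficient modes tokenize only B (or only M) over a
#' vocabulary of size \code{b}.
#'
#' @param bm Data frame from [prefix_bm_series()].
#' @param b Number of bins.
#' @param mode \code{"BM"} (joint, vocab \code{b^2}), \code{"B"} or
#'   \code{"M"} (single coefficient, vocab \code{b}).
#' @return Integer vector of 0-based token indices, padding index for
#'   masked entries.
#' @export
tokenize_bm <- function(bm, b, mode = c("BM", "B", "M")) {
  mode <- match.arg(mode)
  vs <- bm_vocab_size(b, mode)
  tok <- rep.int(vs, nrow(bm))  # padding index
  ok <- bm$valid
  if (any(ok)) {
    if (mode == "BM") {
      dB <- discretize(bm$B[ok], b)
      dM <- discretize(bm$M[ok], b)
      tok[ok] <- dense_vocab_index(dB, dM, b)
    } else if (mode == "B") {
      tok[ok] <- discretize(bm$B[ok], b) - 1L
    } else {
      tok[ok] <- discretize(bm$M[ok], b) - 1L
    }
  }
  as.integer(tok)
}

#' Vocabulary size for a tokenization mode
#'
#' @inheritParams tokenize_bm
#' @return \code{b^2} for joint mode, \code{b} for single-coefficient modes.
#' @export
bm_vocab_size <- function(b, mode = c("BM", "B", "M")) {
  mode <- match.arg(mode)
  b <- as.integer(b)
  if (mode == "BM") b * b else b
}

#' Sinusoidal positional encoding of event times
#'
#' The j-th coordinate of the encoding of time t is \eqn{\sin(\omega_k t)}
#' for \code{j = 2k} and \eqn{\cos(\omega_k t)} for \code{j = 2k + 1}
#' (0-based), with \eqn{\omega_k = 1 / 10000^{2k/d}}. Applied to the raw
#' event timestamps, not their ranks, so the encoding carries metric time:
#' the low-frequency coordinates are nearly linear in t over typical
#' sequence horizons, which is what lets linear readouts recover absolute
#' times.
#'
#' @param t Numeric vector of times.
#' @param d Encoding dimension, even.
#' @return A \code{length(t) x d} matrix with entries in \code{[-1, 1]}.
#' @export
positional_encoding <- function(t, d) {
  d <- as.integer(d)
  if (d < 2L || d %% 2L != 0L) stop("d must be a positive even integer", call. = FALSE)
  k <- seq_len(d / 2L) - 1L
  omega <- 1 / 10000^(2 * k / d)
  ang <- outer(as.numeric(t), omega)  # n x d/2
  z <- matrix(0, nrow = length(t), ncol = d)
  z[, 2L * k + 1L] <- sin(ang)
  z[, 2L * k + 2L] <- cos(ang)
  z
}
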