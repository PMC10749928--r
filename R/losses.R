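#' Squared-error loss of event times
#'
#' \eqn{L_t = \sum_{i=2}^{n} (t_i - \hat t_i)^2}: the prediction for event
#' \code{i} is made from the hidden state of event \code{i - 1}, so the sum
#' starts at the second event.
#'
#' @param t Observed event times for the predicted positions.
#' @param t_hat Predicted event times, aligned with \code{t}.
#' @return Non-negative scalar.
#' @export
loss_time <- function(t, t_hat) {
  if (length(t) != length(t_hat)) stop("t and t_hat must align", call. = FALSE)
  sum((t - t_hat)^2)
}

#' Point-process log-likelihood with piecewise-constant intensity
#'
#' \eqn{LL = \sum_i \log\lambda(t_i) - \int_0^T \lambda\,dt}. Because the
#' model's intensity is constant on each inter-event interval, the
#' non-event integral is the closed form \eqn{\sum_i \lambda_i \Delta t_i}.
#' Returns the log-likelihood itself; negate for minimization.
#'
#' @param event_intensities Intensities evaluated at the event times
#'   included in the likelihood.
#' @param interval_intensities Constant intensity of each interval.
#' @param interval_lengths Lengths of those intervals; together they must
#'   tile the observation window \code{[0, T]} being scored.
#' @return Scalar log-likelihood.
#' @export
loss_loglikelihood <- function(event_intensities, interval_intensities,
                               interval_lengths) {
  if (any(event_intensities <= 0) || any(interval_intensities <= 0)) {
    stop("intensities must be strictly positive", call. = FALSE)
  }
  if (length(interval_intensities) != length(interval_lengths)) {
    stop("interval intensities and lengths must align", call. = FALSE)
  }
  sum(log(event_intensities)) - sum(interval_intensities * interval_lengths)
}

#' Cross-entropy of discretized B & M tokens
#'
#' \eqn{L_{B,M} = -\sum_i \log \hat p_i(\mathrm{token}_i)} over the
#' positions whose ground-truth token is valid (masked prefix positions are
#' excluded by the caller). Predicted probabilities are clamped at 1e-12 so
#' a zero mass on the truth yields a large finite penalty.
#'
#' @param true_tokens Integer vector of 0-based token indices.
#' @param predicted_distributions Matrix, one row per position, columns
#'   summing to 1 over the vocabulary.
#' @return Non-negative scalar.
#' @export
loss_bm_crossentropy <- function(true_tokens, predicted_distributions) {
  if (length(true_tokens) != nrow(predicted_distributions)) {
    stop("one distribution row per token required", call. = FALSE)
  }
  pr <- predicted_distributions[cbind(seq_along(true_tokens), true_tokens + 1L)]
  -sum(log(pmax(pr, 1e-12)))
}

#' Squared-error losses of the burstiness and memory values
#'
#' \eqn{L_B = \sum_i (B_i - \hat B_i)^2} and likewise for M, over valid
#' (unmasked) positions only.
#'
#' @param true_B,pred_B,true_M,pred_M Aligned numeric vectors.
#' @return Named numeric vector \code{c(L_B =, L_M =)}.
#' @export
loss_bm_values <- function(true_B, pred_B, true_M, pred_M) {
  c(L_B = sum((true_B - pred_B)^2), L_M = sum((true_M - pred_M)^2))
}

#' Loss weights
#'
#' The four balance hyperparameters of the total objective
#' \eqn{L = L_t + \alpha_1 L_\lambda + \alpha_2 L_{B,M} + \alpha_3 L_B +
#' \alpha_4 L_M} (with \eqn{L_\lambda = -LL}). Defaults are the tuned
#' full-scale values.
#'
#' @param alpha1,alpha2,alpha3,alpha4 Non-negative reals.
#' @return Named numeric vector of class \code{"loss_weights"}.
#' @export
loss_weights <- function(alpha1 = 1e3, alpha2 = 4e3, alpha3 = 1e4,
                         alpha4 = 1e4) {
  w <- c(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3, alpha4 = alpha4)
  if (any(w < 0)) stop("loss weights must be non-negative", call. = FALSE)
  structure(w, class = "loss_weights")
}

#' Loss weights consistent with an ablation variant
#'
#' Zeroes the weights a variant disables: \code{NoE&NoL} and \code{E&NoL}
#' force \code{alpha2 = alpha3 = alpha4 = 0}; \code{NoE&L} forces
#' \code{alpha2 = 0}; \code{B} forces \code{alpha2 = alpha4 = 0}; \code{M}
#' forces \code{alpha2 = alpha3 = 0}.
#'
#' @param variant Variant name.
#' @param base Weights to restrict (default [loss_weights()]).
#' @export
variant_weights <- function(variant, base = loss_weights()) {
  w <- unclass(base)
  off <- switch(variant,
    "BMT" = character(0),
    "NoE&NoL" = c("alpha2", "alpha3", "alpha4"),
    "E&NoL" = c("alpha2", "alpha3", "alpha4"),
    "NoE&L" = "alpha2",
    "B" = c("alpha2", "alpha4"),
    "M" = c("alpha2", "alpha3"),
    stop("unknown variant: ", variant, call. = FALSE)
  )
  w[off] <- 0
  structure(w, class = "loss_weights")
}

check_variant_weights <- function(variant, weights) {
  allowed <- variant_weights(variant, base = weights)
  bad <- names(which(unclass(weights) != unclass(allowed)))
  if (length(bad)) {
    stop(sprintf("variant %s requires zero %s", variant,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble the weighted loss bundle
#'
#' @param components List with unweighted \code{L_t}, \code{LL},
#'   \code{L_BM} (may be NA when the token head is absent), \code{L_B},
#'   \code{L_M}.
#' @param weights A [loss_weights()] vector, consistent with
#'   \code{variant}.
#' @param variant Ablation variant name (for consistency checking).
#' @return Named list with the five components (\code{L_lambda = -LL}) and
#'   the weighted \code{total}.
#' @export
loss_bundle <- function(components, weights, variant = "BMT") {
  check_variant_weights(variant, weights)
  L_lambda <- -components$LL
  L_BM_term <- if (is.na(components$L_BM)) {
    if (weights[["alpha2"]] > 0) {
      stop("alpha2 > 0 but no token cross-entropy is available", call. = FALSE)
    }
    0
  } else {
    components$L_BM
  }
  total <- components$L_t + weights[["alpha1"]] * L_lambda +
    weights[["alpha2"]] * L_BM_term + weights[["alpha3"]] * components$L_B +
    weights[["alpha4"]] * components$L_M
  if (!is.finite(total)) stop("non-finite total loss", call. = FALSE)
  list(L_t = components$L_t, L_lambda = L_lambda, L_BM = components$L_BM,
       L_B = components$L_B, L_M = components$L_M, total = total)
}
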