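#' Burstiness of an inter-event-time series
#'
#' The burstiness parameter \eqn{B = (\sigma - \langle\tau\rangle) /
#' (\sigma + \langle\tau\rangle)} where \eqn{\sigma} is the population
#' standard deviation (divisor \code{n}) of the inter-event times and
#' \eqn{\langle\tau\rangle} their mean. \code{B = -1} for a perfectly regular
#' sequence, 0 for a Poisson process, and approaches 1 for extreme bursts.
#'
#' The population (rather than sample) standard deviation is used throughout
#' the package; this is the convention of the heterogeneity literature and is
#' what the finite-size correction of [burstiness_corrected()] assumes.
#'
#' @param iets Numeric vector of at least 2 non-negative inter-event times.
#' @return Burstiness in \code{[-1, 1)}.
#' @seealso [burstiness_corrected()], [memory_coefficient()]
#' @examples
#' burstiness(c(2, 2, 2))   # -1, regular
#' burstiness(c(1, 3))      # -1/3
#' @export
burstiness <- function(iets) {
  iets <- as.numeric(iets)
  if (length(iets) < 2L) stop("need at least 2 inter-event times", call. = FALSE)
  if (any(iets < 0)) stop("inter-event times must be non-negative", call. = FALSE)
  m <- mean(iets)
  s <- sqrt(mean((iets - m)^2))
  if (s == 0 && m == 0) {
    stop("burstiness undefined: all inter-event times are zero", call. = FALSE)
  }
  (s - m) / (s + m)
}

#' Coefficient of variation of inter-event times
#'
#' \eqn{r = \sigma / \langle\tau\rangle} with population \eqn{\sigma}.
#'
#' @inheritParams burstiness
#' @return Non-negative real.
#' @export
iet_cv <- function(iets) {
  iets <- as.numeric(iets)
  if (length(iets) < 2L) stop("need at least 2 inter-event times", call. = FALSE)
  m <- mean(iets)
  if (m <= 0) stop("mean inter-event time must be positive", call. = FALSE)
  sqrt(mean((iets - m)^2)) / m
}

#' Finite-size-corrected burstiness
#'
#' For short sequences the empirical coefficient of variation is biased, so
#' the plain burstiness of a finite Poissonian sequence is systematically
#' negative. The corrected parameter
#' \deqn{B_n = \frac{\sqrt{n+1}\,r - \sqrt{n-1}}
#'                  {(\sqrt{n+1} - 2)\,r + \sqrt{n-1}}}
#' removes this bias: its expectation is close to 0 for Poissonian sequences
#' of any length, and it converges to \eqn{(r-1)/(r+1)} as \eqn{n \to \infty}.
#'
#' Here \code{n} is the number of *events* in the (sub)sequence, so \code{r}
#' is computed from its \code{n - 1} inter-event times. Passing \code{iets}
#' fills both arguments consistently; alternatively supply \code{r} and
#' \code{n} directly to test other conventions.
#'
#' @param r Coefficient of variation (population). Ignored when \code{iets}
#'   is given.
#' @param n Number of events. Ignored when \code{iets} is given.
#' @param iets Optional inter-event-time vector; implies
#'   \code{r = iet_cv(iets)} and \code{n = length(iets) + 1}.
#' @return Corrected burstiness in \code{[-1, 1]}.
#' @examples
#' burstiness_corrected(r = 0, n = 100)  # -1
#' burstiness_corrected(r = 1, n = 5)    # ~0.1835
#' @export
burstiness_corrected <- function(r = NULL, n = NULL, iets = NULL) {
  if (!is.null(iets)) {
    r <- iet_cv(iets)
    n <- length(iets) + 1L
  }
  if (is.null(r) || is.null(n)) stop("supply either iets or both r and n", call. = FALSE)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (r < 0) stop("r must be non-negative", call. = FALSE)
  sp <- sqrt(n + 1)
  sm <- sqrt(n - 1)
  den <- (sp - 2) * r + sm
  if (den <= 0) {
    stop(sprintf(
      "corrected burstiness undefined: denominator %.3g <= 0 (n = %d, r = %.3g)",
      den, as.integer(n), r
    ), call. = FALSE)
  }
  (sp * r - sm) / den
}

#' Memory coefficient of an inter-event-time series
#'
#' The lag-1 Pearson correlation between consecutive inter-event times:
#' positive when long gaps tend to follow long gaps, negative when long and
#' short gaps alternate, 0 for renewal (memoryless) sequences.
#'
#' @inheritParams burstiness
#' @param on_degenerate What to do when one of the lag-shifted subseries has
#'   zero variance: \code{"error"} (default) or \code{"zero"} to return 0.
#' @return Correlation in \code{[-1, 1]}.
#' @examples
#' memory_coefficient(c(1, 2, 1, 2, 1))  # -1
#' memory_coefficient(c(1, 2, 3, 4))     # 1
#' @export
memory_coefficient <- function(iets, on_degenerate = c("error", "zero")) {
  on_degenerate <- match.arg(on_degenerate)
  iets <- as.numeric(iets)
  k <- length(iets)
  if (k < 3L) stop("need at least 3 inter-event times", call. = FALSE)
  x <- iets[-k]
  y <- iets[-1]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    if (on_degenerate == "zero") return(0)
    stop("memory coefficient undefined: zero variance in a lagged subseries",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Per-event prefix burstiness and memory series
#'
#' For each event \code{i} the statistics are recomputed from the prefix
#' \code{t_1..t_i} alone, exactly as they would be for the truncated
#' sequence, so entry \code{i} is causal by construction. The burstiness is
#' the finite-size-corrected form with \code{n = i} events; the memory
#' coefficient is the lag-1 Pearson correlation of the prefix gaps.
#'
#' Entries for the first three events are masked invalid: with so few events
#' the statistics are dominated by noise (and the memory coefficient needs at
#' least 3 gaps). Degenerate later prefixes (zero variance) are likewise
#' masked rather than raised, because model pipelines consume whole
#' sequences. For the final event \code{B_n} and \code{M_n} equal the
#' whole-sequence statistics.
#'
#' @param seq An [event_sequence()].
#' @return A data frame with columns \code{event} (index), \code{B},
#'   \code{M}, \code{valid}. Masked entries hold \code{NA}.
#' @export
prefix_bm_series <- function(seq) {
  ts <- if (is_event_sequence(seq)) seq$timestamps else as.numeric(seq)
  n <- length(ts)
  iets <- diff(ts)
  B <- rep(NA_real_, n)
  M <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i <= 3L) next
    pre <- iets[seq_len(i - 1L)]
    Bi <- tryCatch(burstiness_corrected(iets = pre), error = function(e) NA_real_)
    Mi <- tryCatch(memory_coefficient(pre), error = function(e) NA_real_)
    if (!is.na(Bi) && !is.na(Mi)) {
      B[i] <- Bi
      M[i] <- Mi
      valid[i] <- TRUE
    }
  }
  data.frame(event = seq_len(n), B = B, M = M, valid = valid)
}

#' Heterogeneity summary of one sequence
#'
#' @param seq An [event_sequence()].
#' @return A one-row data frame with \code{n_events}, \code{mean_iet},
#'   \code{sd_iet} (population), \code{B} (uncorrected), \code{B_n}
#'   (finite-size corrected), and \code{M}. Statistics whose preconditions
#'   fail are \code{NA}.
#' @export
heterogeneity_summary <- function(seq) {
  iets <- compute_iets(seq)
  m <- mean(iets)
  s <- sqrt(mean((iets - m)^2))
  data.frame(
    n_events = length(iets) + 1L,
    mean_iet = m,
    sd_iet = s,
    B = tryCatch(burstiness(iets), error = function(e) NA_real_),
    B_n = tryCatch(burstiness_corrected(iets = iets), error = function(e) NA_real_),
    M = tryCatch(memory_coefficient(iets), error = function(e) NA_real_)
  )
}

#' Ensemble statistics of a dataset
#'
#' Computes, for every sequence, the mean inter-event time, the
#' finite-size-corrected burstiness of the full sequence, and the memory
#' coefficient, and then summarizes each across the ensemble by its mean and
#' standard deviation (the per-sequence-ensemble convention: statistics of
#' per-sequence values, not pooled events). Sequences failing a metric
#' precondition contribute \code{NA} to that column and are dropped from the
#' corresponding ensemble summary; their count is reported.
#'
#' @param dataset An [event_dataset()].
#' @return A list with \code{per_sequence} (data frame, one row per
#'   sequence), \code{ensemble} (data frame with rows \code{mean} and
#'   \code{sd} for columns \code{mean_iet}, \code{B}, \code{M}), and
#'   \code{n_skipped} (named vector of NA counts per column).
#' @export
dataset_summary <- function(dataset) {
  if (!length(dataset)) stop("empty dataset", call. = FALSE)
  per <- do.call(rbind, lapply(dataset, heterogeneity_summary))
  rownames(per) <- NULL
  cols <- c(mean_iet = "mean_iet", B = "B_n", M = "M")
  ens <- sapply(cols, function(cl) {
    v <- per[[cl]]
    v <- v[!is.na(v)]
    # population SD so a single-sequence ensemble reports 0, not NA
    c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
  })
  ens <- as.data.frame(ens)
  names(ens) <- names(cols)
  skipped <- vapply(cols, function(cl) sum(is.na(per[[cl]])), integer(1))
  if (any(skipped > 0)) {
    message("dataset_summary: sequences skipped per metric: ",
            paste(names(skipped), skipped, sep = "=", collapse = ", "))
  }
  list(per_sequence = per, ensemble = ens, n_skipped = skipped)
}

#' Log-binned inter-event-time histogram
#'
#' Histogram of inter-event times on geometrically spaced bins, normalized
#' as a probability density (bin mass divided by linear bin width), the
#' standard way to visualize heavy-tailed inter-event-time distributions.
#' The density integrates to 1 over the binned range.
#'
#' @param iets Strictly positive inter-event times.
#' @param bins_per_decade Number of bins per factor of 10 (default 10).
#' @return Data frame with \code{bin_lo}, \code{bin_hi}, \code{bin_center}
#'   (geometric midpoint), \code{count}, and \code{density}.
#' @export
log_binned_iet_histogram <- function(iets, bins_per_decade = 10L) {
  iets <- as.numeric(iets)
  if (!length(iets)) stop("no inter-event times", call. = FALSE)
  if (any(iets <= 0)) stop("inter-event times must be positive for log binning",
                           call. = FALSE)
  if (bins_per_decade < 1L) stop("bins_per_decade must be >= 1", call. = FALSE)
  lo <- floor(log10(min(iets)) * bins_per_decade)
  hi <- ceiling(log10(max(iets)) * bins_per_decade)
  if (hi == lo) hi <- lo + 1L  # all values in one bin
  edges <- 10^(seq(lo, hi) / bins_per_decade)
  # guard against values landing exactly on the top edge
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12)
  counts <- graphics::hist(iets, breaks = edges, plot = FALSE, right = FALSE)$counts
  widths <- diff(edges)
  data.frame(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_center = sqrt(edges[-length(edges)] * edges[-1]),
    count = counts,
    density = counts / (sum(counts) * widths)
  )
}
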