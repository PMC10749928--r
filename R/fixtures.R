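#' Deterministic fixture datasets
#'
#' Small datasets for fast tests and examples: 20 sequences per synthetic
#' family with 30-100 events each, plus their concatenation as a mixed
#' dataset. Fully deterministic given the seed.
#'
#' @param seed Integer master seed; each family uses a fixed offset of it.
#' @param n_sequences Sequences per family.
#' @param n_range Event-count range per sequence.
#' @return Named list of [event_dataset()]s: \code{powerlaw},
#'   \code{exponential}, \code{self_correcting}, \code{mixed}.
#' @export
fixture_suite <- function(seed = 42L, n_sequences = 20L,
                          n_range = c(30L, 100L)) {
  pl <- generate_powerlaw_dataset(n_sequences, seed = seed, n_range = n_range)
  ex <- generate_exponential_dataset(n_sequences, seed = seed + 1L,
                                     n_range = n_range)
  sc <- generate_self_correcting_dataset(n_sequences, seed = seed + 2L,
                                         n_range = n_range)
  list(
    powerlaw = pl,
    exponential = ex,
    self_correcting = sc,
    mixed = event_dataset(c(unclass(pl), unclass(ex), unclass(sc)))
  )
}
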