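#' Construct an event sequence
#'
#' An event sequence is an ordered set of event timestamps \code{t_1 < t_2 <
#' ... < t_n} observed on the interval \code{[0, observation_end]}. Timestamps
#' may be in any time unit as long as it is used consistently; all statistics
#' returned by the package inherit that unit.
#'
#' @param timestamps Numeric vector of strictly increasing event times,
#'   length at least 2.
#' @param observation_end End of the observation window \code{T}; defaults to
#'   the last event time. Must satisfy \code{T >= t_n}.
#' @param label Optional character label carried through IO round trips.
#' @param metadata Optional named list of generator parameters or other
#'   provenance, preserved by [write_sequences()].
#'
#' @return An object of class \code{"event_sequence"}: a list with elements
#'   \code{timestamps}, \code{observation_end}, \code{label}, \code{metadata}.
#' @examples
#' seq <- event_sequence(c(0.5, 1.2, 3.0, 3.1))
#' compute_iets(seq)
#' @export
event_sequence <- function(timestamps, observation_end = NULL, label = NULL,
                           metadata = NULL) {
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) < 2L) {
    stop("an event sequence needs at least 2 events", call. = FALSE)
  }
  if (anyNA(timestamps) || any(!is.finite(timestamps))) {
    stop("timestamps must be finite and non-missing", call. = FALSE)
  }
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(observation_end)) {
    observation_end <- timestamps[length(timestamps)]
  }
  if (observation_end < timestamps[length(timestamps)]) {
    stop("observation_end must not precede the last event", call. = FALSE)
  }
  structure(
    list(
      timestamps = timestamps,
      observation_end = as.numeric(observation_end),
      label = label,
      metadata = metadata
    ),
    class = "event_sequence"
  )
}

#' @export
print.event_sequence <- function(x, ...) {
  n <- length(x$timestamps)
  cat(sprintf(
    "<event_sequence> %d events on [0, %g]%s\n", n, x$observation_end,
    if (is.null(x$label)) "" else paste0(" label=", x$label)
  ))
  invisible(x)
}

#' @export
length.event_sequence <- function(x) length(x$timestamps)

is_event_sequence <- function(x) inherits(x, "event_sequence")

#' Inter-event times of a sequence
#'
#' Returns the \code{n - 1} consecutive gaps \code{tau_i = t_{i+1} - t_i}.
#' Generated sequences always have strictly positive gaps; the
#' [event_sequence()] validator enforces this, so observed data containing
#' tied timestamps must be de-duplicated (or jittered) before construction.
#'
#' @param seq An [event_sequence()], or a bare numeric vector of strictly
#'   increasing timestamps.
#' @return Numeric vector of length \code{n - 1}.
#' @export
compute_iets <- function(seq) {
  ts <- if (is_event_sequence(seq)) seq$timestamps else as.numeric(seq)
  if (length(ts) < 2L) stop("need at least 2 events", call. = FALSE)
  d <- diff(ts)
  if (any(d <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  d
}

#' Bundle event sequences into a dataset
#'
#' @param sequences List of [event_sequence()] objects.
#' @return An object of class \code{"event_dataset"} (a list).
#' @export
event_dataset <- function(sequences) {
  ok <- vapply(sequences, is_event_sequence, logical(1))
  if (!all(ok)) stop("all elements must be event_sequence objects", call. = FALSE)
  structure(sequences, class = "event_dataset")
}

#' @export
print.event_dataset <- function(x, ...) {
  ns <- vapply(x, length, integer(1))
  cat(sprintf(
    "<event_dataset> %d sequences, %d-%d events (total %d)\n",
    length(x), if (length(ns)) min(ns) else 0L,
    if (length(ns)) max(ns) else 0L, sum(ns)
  ))
  invisible(x)
}

#' @export
`[.event_dataset` <- function(x, i) {
  structure(unclass(x)[i], class = "event_dataset")
}

#' Read event sequences from a JSON Lines file
#'
#' One JSON object per line with a \code{timestamps} array and optional
#' \code{label} and \code{metadata} fields. Malformed lines (bad JSON, missing
#' or non-increasing timestamps) are skipped with a warning that lists the
#' offending line numbers.
#'
#' @param path Path to a JSON Lines file.
#' @return An [event_dataset()].
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty dataset file: ", path, call. = FALSE)
    return(event_dataset(list()))
  }
  bad <- integer(0)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    seq <- NULL
    if (!is.null(rec) && !is.null(rec$timestamps)) {
      seq <- tryCatch(
        event_sequence(
          rec$timestamps,
          observation_end = rec$observation_end,
          label = rec$label,
          metadata = rec$metadata
        ),
        error = function(e) NULL
      )
    }
    if (is.null(seq)) bad <- c(bad, i) else out[[i]] <- seq
  }
  if (length(bad)) {
    warning(sprintf(
      "skipped %d malformed record(s) at line(s): %s", length(bad),
      paste(utils::head(bad, 20L), collapse = ", ")
    ), call. = FALSE)
    out <- out[-bad]
  }
  event_dataset(Filter(Negate(is.null), out))
}

#' Write event sequences to a JSON Lines file
#'
#' Fields are emitted in a fixed order (\code{timestamps},
#' \code{observation_end}, \code{label}, \code{metadata}) and numeric values
#' are serialized at full double precision, so write-then-read round trips
#' are lossless and output is byte-stable for a fixed dataset.
#'
#' @param dataset An [event_dataset()] (or plain list of sequences).
#' @param path Output file path.
#' @export
write_sequences <- function(dataset, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (seq in dataset) {
    rec <- list(timestamps = seq$timestamps,
                observation_end = seq$observation_end)
    if (!is.null(seq$label)) rec$label <- seq$label
    if (!is.null(seq$metadata)) rec$metadata <- seq$metadata
    # digits = I(17): enough significant digits to round-trip doubles exactly
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17)), con)
  }
  invisible(path)
}

#' Import whitespace-delimited timestamp files
#'
#' Each non-empty line holds one sequence: timestamps separated by
#' whitespace. Intended for quickly importing external event data.
#'
#' @param path Input path.
#' @return An [event_dataset()].
#' @export
read_timestamp_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  seqs <- lapply(lines, function(l) {
    event_sequence(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  })
  event_dataset(seqs)
}
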