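#' Spike train event data
#'
#' Container for parallel spike trains recorded from a neural population:
#' a list of (neuron, time) events together with the population size and the
#' recording duration. Neuron ids are 0-based integers, times are seconds.
#'
#' @param events data frame with columns `neuron_id` (integer >= 0) and
#'   `time` (seconds, >= 0).
#' @param n_neurons population size; defaults to `max(neuron_id) + 1`.
#' @param duration recording duration in seconds; defaults to the last spike
#'   time.
#' @return An object of class `spike_data` with fields `events`,
#'   `n_neurons` and `duration`.
#' @export
spike_data <- function(events, n_neurons = NULL, duration = NULL) {
  stopifnot(is.data.frame(events))
  if (!all(c("neuron_id", "time") %in% names(events))) {
    stop("`events` must have columns `neuron_id` and `time`")
  }
  events <- data.frame(neuron_id = as.integer(events$neuron_id),
                       time = as.numeric(events$time))
  if (nrow(events) > 0) {
    if (anyNA(events)) stop("events contain missing values")
    if (any(events$neuron_id < 0L)) stop("negative neuron ids are not allowed")
    if (any(events$time < 0)) stop("negative spike times are not allowed")
  }
  n_neurons <- as.integer(n_neurons %||%
                            (if (nrow(events)) max(events$neuron_id) + 1L else 0L))
  if (nrow(events) && any(events$neuron_id >= n_neurons)) {
    bad <- which(events$neuron_id >= n_neurons)[1]
    stop(sprintf("neuron id %d (row %d) is outside population of size %d",
                 events$neuron_id[bad], bad, n_neurons))
  }
  duration <- as.numeric(duration %||% (if (nrow(events)) max(events$time) else 0))
  if (nrow(events) && any(events$time > duration)) {
    stop("spike times exceed the stated duration")
  }
  events <- events[order(events$time, events$neuron_id), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, n_neurons = n_neurons, duration = duration),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d events, %d neurons, %.3f s\n",
              nrow(x$events), x$n_neurons, x$duration))
  invisible(x)
}

#' Per-neuron spike counts
#'
#' Total number of spikes emitted by each neuron over the whole recording.
#'
#' @param data a [spike_data] object.
#' @return Integer vector of length `n_neurons` (0-based neuron `i` at
#'   position `i + 1`).
#' @export
spike_counts <- function(data) {
  stopifnot(inherits(data, "spike_data"))
  tabulate(data$events$neuron_id + 1L, nbins = data$n_neurons)
}

#' Read spike trains from a delimited text file
#'
#' The file must be comma-separated with a header line `neuron_id,time`;
#' one event per row, times in seconds, neuron ids 0-based.
#'
#' @param path file path.
#' @param n_neurons optional population size (otherwise inferred).
#' @param duration optional recording duration override.
#' @return A [spike_data] object.
#' @export
read_spikes <- function(path, n_neurons = NULL, duration = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("empty spike file: ", path)
  if (!all(c("neuron_id", "time") %in% names(df))) {
    stop("spike file must have header `neuron_id,time`")
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time))) |
                 !is.finite(suppressWarnings(as.numeric(df$neuron_id))))
  if (length(bad)) {
    stop(sprintf("malformed row %d in %s", bad[1] + 1L, path))
  }
  spike_data(df, n_neurons = n_neurons, duration = duration)
}

#' Write spike trains to a delimited text file
#'
#' @param data a [spike_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(data, path) {
  stopifnot(inherits(data, "spike_data"))
  write.csv(data$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
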