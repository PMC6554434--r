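#' Sliding-window configuration
#'
#' Defines how a recording is segmented: windows of length `window_s`
#' seconds, divided into `L = window_s / bin_s` bins, placed every
#' `stride_s` seconds starting at t = 0. The default stride equals the
#' window length (non-overlapping windows).
#'
#' @param window_s window length T_w in seconds.
#' @param bin_s bin size b in seconds; `window_s / bin_s` must be an integer.
#' @param stride_s stride between window starts in seconds (> 0).
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_s, bin_s, stride_s = window_s) {
  stopifnot(window_s > 0, bin_s > 0, stride_s > 0)
  L <- window_s / bin_s
  if (abs(L - round(L)) > 1e-8) {
    stop("window_s must be an integer multiple of bin_s")
  }
  structure(list(window_s = window_s, bin_s = bin_s, stride_s = stride_s,
                 n_bins = as.integer(round(L))),
            class = "window_config")
}

#' Segment spike data into binned time windows
#'
#' Cuts the recording into windows starting at 0, `stride_s`, 2 `stride_s`,
#' ... (only windows fully inside `[0, duration]` are kept) and counts, for
#' each window, the spikes of every neuron in each of its `L` bins. Bins are
#' half-open `[start, end)`: a spike exactly on a window's right edge belongs
#' to the next window.
#'
#' Counts are stored sparsely (one row per non-zero cell); use
#' [window_matrix()] to materialise a single window as a dense N x L matrix.
#'
#' @param data a [spike_data] object.
#' @param cfg a [window_config].
#' @return An object of class `window_set` with fields `spikes` (data frame
#'   `window`, `neuron`, `bin`, `count`; `neuron` and `bin` 1-based),
#'   `starts`, `n_windows`, `n_neurons`, `n_bins`, `config`.
#' @export
segment_windows <- function(data, cfg) {
  stopifnot(inherits(data, "spike_data"), inherits(cfg, "window_config"))
  if (cfg$window_s > data$duration + 1e-12) {
    stop("window length exceeds the recording duration")
  }
  M <- floor((data$duration - cfg$window_s) / cfg$stride_s + 1e-9) + 1L
  starts <- (seq_len(M) - 1) * cfg$stride_s
  ev <- data$events
  L <- cfg$n_bins
  if (nrow(ev) == 0) {
    spikes <- data.frame(window = integer(0), neuron = integer(0),
                         bin = integer(0), count = integer(0))
  } else if (abs(cfg$stride_s - cfg$window_s) < 1e-12) {
    # non-overlapping fast path: window and bin by arithmetic
    w <- floor(ev$time / cfg$window_s + 1e-9) + 1L
    keep <- w >= 1L & w <= M
    t0 <- ev$time[keep] - (w[keep] - 1) * cfg$window_s
    b <- pmin(floor(t0 / cfg$bin_s + 1e-9) + 1L, L)
    spikes <- count_cells(w[keep], ev$neuron_id[keep] + 1L, b)
  } else {
    tt <- ev$time
    res <- vector("list", M)
    for (k in seq_len(M)) {
      lo <- findInterval(starts[k] - 1e-12, tt) + 1L
      hi <- findInterval(starts[k] + cfg$window_s - 1e-12, tt)
      if (hi < lo) next
      idx <- lo:hi
      b <- pmin(floor((tt[idx] - starts[k]) / cfg$bin_s + 1e-9) + 1L, L)
      res[[k]] <- count_cells(rep.int(k, length(idx)), ev$neuron_id[idx] + 1L, b)
    }
    spikes <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    if (is.null(spikes)) {
      spikes <- data.frame(window = integer(0), neuron = integer(0),
                           bin = integer(0), count = integer(0))
    }
  }
  structure(list(spikes = spikes, starts = starts, n_windows = M,
                 n_neurons = data$n_neurons, n_bins = L, config = cfg),
            class = "window_set")
}

# aggregate (window, neuron, bin) triplets into counts, sorted by
# window then neuron then bin (the order the scoring kernel expects)
count_cells <- function(w, n, b) {
  key <- paste(w, n, b)
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  out <- data.frame(window = as.integer(parts[, 1]),
                    neuron = as.integer(parts[, 2]),
                    bin = as.integer(parts[, 3]),
                    count = as.integer(agg))
  out[order(out$window, out$neuron, out$bin), , drop = FALSE]
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows (L = %d bins of %.3g s), %d neurons\n",
              x$n_windows, x$n_bins, x$config$bin_s, x$n_neurons))
  invisible(x)
}

#' Materialise one window as a dense count matrix
#'
#' @param ws a `window_set` from [segment_windows()].
#' @param k window index (1-based).
#' @return Numeric N x L matrix of spike counts (neurons x bins).
#' @export
window_matrix <- function(ws, k) {
  stopifnot(inherits(ws, "window_set"), k >= 1, k <= ws$n_windows)
  W <- matrix(0, ws$n_neurons, ws$n_bins)
  sp <- ws$spikes[ws$spikes$window == k, , drop = FALSE]
  if (nrow(sp)) W[cbind(sp$neuron, sp$bin)] <- sp$count
  W
}

# 0-based pointer vector into ws$spikes grouped by window (length M + 1),
# assuming ws$spikes is sorted by window
window_ptr <- function(ws) {
  counts <- tabulate(ws$spikes$window, nbins = ws$n_windows)
  as.integer(c(0L, cumsum(counts)))
}
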