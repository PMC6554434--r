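#' Classic Needleman-Wunsch similarity between two strings
#'
#' Scores the maximal number of order-preserving character coincidences
#' between two strings (no gap penalty by default) with the standard dynamic
#' programme, and recovers a maximally coincident common subsequence by
#' traceback: the characters appearing after every diagonal move.
#'
#' @param s1,s2 character strings. `#` is reserved as the null prefix.
#' @param match_score score for a character coincidence (default 1).
#' @param gap_score score for an insertion/deletion (default 0).
#' @return A list with `score` and `subsequence`.
#' @examples
#' nw_score_strings("ATCGTAC", "ATGTTAT") # score 5, "ATGTA"
#' @export
nw_score_strings <- function(s1, s2, match_score = 1, gap_score = 0) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(list(score = 0, subsequence = ""))
  eps <- matrix(0, n + 1, m + 1)
  # moves: 0 start, 1 up (gap in s2 direction), 2 right, 3 diagonal
  mv <- matrix(0L, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      up <- eps[i - 1, j] + gap_score
      right <- eps[i, j - 1] + gap_score
      diag <- eps[i - 1, j - 1] +
        (if (a[i - 1] == b[j - 1] && a[i - 1] != "#") match_score else 0)
      best <- up; m_ <- 1L
      if (right >= best) { best <- right; m_ <- 2L }
      if (diag >= best) { best <- diag; m_ <- 3L }
      eps[i, j] <- best
      mv[i, j] <- m_
    }
  }
  chars <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 && j > 1) {
    if (mv[i, j] == 3L) {
      if (a[i - 1] == b[j - 1]) chars <- c(a[i - 1], chars)
      i <- i - 1; j <- j - 1
    } else if (mv[i, j] == 1L) i <- i - 1 else j <- j - 1
  }
  list(score = eps[n + 1, m + 1], subsequence = paste(chars, collapse = ""))
}

#' Edit similarity between two binned activity windows
#'
#' Extended Needleman-Wunsch similarity for neural population activity:
#' the windows' bins play the role of characters and a coincidence between
#' bin i of `W1` and bin j of `W2` scores their inner product
#' `r_i . r_j`. A run of g consecutive gaps in either direction costs
#' `exp(alpha * g)` (the exponential gap penalty; `alpha` sets the tolerance
#' for time lags between consecutive matches), and cell scores are floored
#' at zero so the alignment can restart anywhere within the windows
#' (local alignment: sequence onsets are unknown in neural data).
#'
#' @param W1,W2 numeric N x L matrices (neurons x bins) with equal
#'   dimensions. Real-valued entries (e.g. z-scored rates or profiles) are
#'   allowed.
#' @param alpha gap-penalty weight, >= 0.
#' @param with_traceback if `TRUE`, also return the matched bin pairs.
#' @return A list with `score` (the edit similarity E >= 0) and, with
#'   traceback, `pairs`: a matrix of matched (bin in W1, bin in W2) pairs,
#'   strictly increasing in both coordinates.
#' @export
edit_similarity <- function(W1, W2, alpha = 1, with_traceback = FALSE) {
  stopifnot(is.matrix(W1), is.matrix(W2), alpha >= 0)
  if (!all(dim(W1) == dim(W2))) {
    stop("W1 and W2 must have identical dimensions (same N and L)")
  }
  P <- crossprod(W1, W2) # P[i, j] = r_i(W1) . r_j(W2)
  if (with_traceback) {
    res <- cpp_dp_align(P, alpha)
    list(score = res$score, pairs = res$pairs)
  } else {
    list(score = cpp_dp_score(P, alpha))
  }
}

#' Edit similarities for a set of candidate window pairs
#'
#' Computes the edit similarity for each listed pair of windows of a
#' [segment_windows()] result (typically the candidate pairs surviving
#' MinHash banding) and returns them as a sparse similarity store.
#'
#' @param ws a `window_set`.
#' @param pairs two-column integer matrix or data frame of window indices
#'   (k, k'), k < k'.
#' @param alpha gap-penalty weight.
#' @return An object of class `similarity_store`: list with `pairs` (data
#'   frame `i`, `j`, `E`), `n_windows` and `e_max`.
#' @export
score_candidate_pairs <- function(ws, pairs, alpha = 1) {
  stopifnot(inherits(ws, "window_set"))
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) == 0) stop("no candidate pairs to score")
  E <- cpp_score_pairs(window_ptr(ws), ws$spikes$neuron, ws$spikes$bin,
                       as.numeric(ws$spikes$count), pairs, ws$n_bins, alpha)
  similarity_store(data.frame(i = pairs[, 1], j = pairs[, 2], E = E),
                   ws$n_windows)
}

#' Sparse symmetric store of pairwise edit similarities
#'
#' @param pairs data frame with columns `i`, `j` (window indices, i < j) and
#'   `E` (similarity >= 0).
#' @param n_windows total number of windows the indices refer to.
#' @return A `similarity_store` object.
#' @export
similarity_store <- function(pairs, n_windows) {
  stopifnot(is.data.frame(pairs), all(c("i", "j", "E") %in% names(pairs)))
  swap <- pairs$i > pairs$j
  if (any(swap)) {
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
  }
  pairs <- pairs[!duplicated(pairs[c("i", "j")]), , drop = FALSE]
  structure(list(pairs = pairs, n_windows = as.integer(n_windows),
                 e_max = if (nrow(pairs)) max(pairs$E) else -Inf),
            class = "similarity_store")
}

#' @export
print.similarity_store <- function(x, ...) {
  tot <- x$n_windows * (x$n_windows - 1) / 2
  cat(sprintf("<similarity_store> %d / %.0f pairs computed (%.1f%%), E_max = %.4g\n",
              nrow(x$pairs), tot, 100 * nrow(x$pairs) / max(tot, 1), x$e_max))
  invisible(x)
}

#' Distance transform of a similarity store
#'
#' Converts edit similarities to distances, `D(k, k') = E_max - E(k, k')`,
#' where `E_max` is the maximum over all computed pairs. Pairs that were
#' never computed (pruned by the MinHash stage) are assigned the maximal
#' distance `E_max`.
#'
#' @param store a `similarity_store`.
#' @return An object of class `distance_store` (same layout, column `D`
#'   instead of `E`); use [as.matrix()] to get the dense distance matrix.
#' @export
distance_from_similarity <- function(store) {
  stopifnot(inherits(store, "similarity_store"))
  if (nrow(store$pairs) == 0) stop("empty similarity store")
  structure(list(pairs = data.frame(i = store$pairs$i, j = store$pairs$j,
                                    D = store$e_max - store$pairs$E),
                 n_windows = store$n_windows, e_max = store$e_max),
            class = "distance_store")
}

#' @export
as.matrix.distance_store <- function(x, ...) {
  D <- matrix(x$e_max, x$n_windows, x$n_windows)
  diag(D) <- 0
  idx <- cbind(x$pairs$i, x$pairs$j)
  D[idx] <- x$pairs$D
  D[idx[, 2:1, drop = FALSE]] <- x$pairs$D
  D
}
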