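#' Active-neuron masks of binned windows
#'
#' Boolean vector per window: element i is 1 iff neuron i fires at least
#' once anywhere in the window. These masks are the sets whose Jaccard
#' similarity the MinHash stage estimates.
#'
#' @param ws a `window_set` from [segment_windows()].
#' @return Logical N x M matrix (neurons x windows).
#' @export
activity_masks <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  m <- matrix(FALSE, ws$n_neurons, ws$n_windows)
  if (nrow(ws$spikes)) m[cbind(ws$spikes$neuron, ws$spikes$window)] <- TRUE
  m
}

#' Jaccard similarity of two Boolean vectors
#'
#' `|intersection| / |union|` of the active sets. Two all-zero vectors have
#' similarity 0 by convention.
#'
#' @param w1,w2 logical (or 0/1) vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(w1, w2) {
  stopifnot(length(w1) == length(w2))
  w1 <- as.logical(w1); w2 <- as.logical(w2)
  u <- sum(w1 | w2)
  if (u == 0) return(0)
  sum(w1 & w2) / u
}

#' Probability that banded MinHash signatures collide
#'
#' For two windows with Jaccard similarity `s`, the probability that their
#' signature columns agree on all `l_rows` rows of at least one of `b_bands`
#' bands: `p(s) = 1 - (1 - s^l)^b`. This S-shaped curve is what turns the
#' banding scheme into a soft similarity threshold.
#'
#' @param s Jaccard similarity in \[0, 1\] (vectorised).
#' @param b_bands number of bands b.
#' @param l_rows rows per band l.
#' @return Probability in \[0, 1\].
#' @export
candidate_probability <- function(s, b_bands, l_rows) {
  stopifnot(b_bands >= 1, l_rows >= 1)
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  1 - (1 - s^l_rows)^b_bands
}

#' Data-driven Jaccard thresholds for band selection
#'
#' Estimates, under an independent-Poisson assumption at each neuron's
#' empirical firing rate, the chance Jaccard similarity between two windows
#' (`jaccard1`) and the similarity expected when the windows additionally
#' share `n3` coincidently active neurons (`jaccard2`). With
#' `p_i = 1 - (1 - (#_i / T) b)^(L)` the probability that neuron i is active
#' in a window (b bin size, L bins), `N1 = sum p_i` is the expected number
#' of active neurons per window and `N2 = sum p_i^2` the expected number of
#' coincidently active neurons in a window pair; then
#' `jaccard1 = N2 / (2 N1 - N2)` and
#' `jaccard2 = (N2 + N3) / (2 N1 - N2 - N3)`.
#'
#' @param data a [spike_data] object.
#' @param cfg a [window_config].
#' @param n3 assumed number of extra coincident neurons in signal window
#'   pairs (roughly half the expected assembly size is a sensible value).
#' @return List with `jaccard1`, `jaccard2`, `n1`, `n2`, `p_active`.
#' @export
estimate_jaccard_thresholds <- function(data, cfg, n3 = 10) {
  stopifnot(inherits(data, "spike_data"), inherits(cfg, "window_config"),
            data$duration > 0, n3 >= 0)
  rate <- spike_counts(data) / data$duration
  p_bin <- pmin(rate * cfg$bin_s, 1)
  p_i <- 1 - (1 - p_bin)^cfg$n_bins
  n1 <- sum(p_i)
  n2 <- sum(p_i^2)
  j1 <- if (n1 > 0) n2 / (2 * n1 - n2) else 0
  denom <- 2 * n1 - n2 - n3
  if (denom <= 0) stop("n3 too large for this population activity")
  j2 <- (n2 + n3) / denom
  if (j2 > 1) stop("n3 too large: implied jaccard2 exceeds 1")
  list(jaccard1 = j1, jaccard2 = j2, n1 = n1, n2 = n2, p_active = p_i)
}

#' Choose MinHash band parameters separating two Jaccard levels
#'
#' Brute-force search over `b_bands` and `l_rows` in `[1, search_max]` for a
#' pair such that chance-level pairs are unlikely to become candidates
#' (`p(jaccard1) <= p_low`) while signal-level pairs are likely retained
#' (`p(jaccard2) >= p_high`). Among feasible pairs the cheapest signature
#' (minimal `n = b * l`) is returned, ties broken towards smaller `l_rows`.
#'
#' @param jaccard1,jaccard2 the two similarity levels, `jaccard1 < jaccard2`.
#' @param p_low maximal candidate probability at `jaccard1` (default 0.1).
#' @param p_high minimal candidate probability at `jaccard2` (default 0.8).
#' @param search_max upper bound of the grid (default 50).
#' @return An object of class `band_params`: list with `b_bands`, `l_rows`,
#'   `n_hash`, and the thresholds used.
#' @export
select_band_params <- function(jaccard1, jaccard2, p_low = 0.1, p_high = 0.8,
                               search_max = 50) {
  stopifnot(jaccard1 >= 0, jaccard2 <= 1)
  if (jaccard1 >= jaccard2) stop("jaccard1 must be smaller than jaccard2")
  grid <- expand.grid(b = seq_len(search_max), l = seq_len(search_max))
  ok <- candidate_probability(jaccard1, grid$b, grid$l) <= p_low &
    candidate_probability(jaccard2, grid$b, grid$l) >= p_high
  if (!any(ok)) {
    stop("no feasible (b, l) pair in [1, ", search_max, "] separates ",
         sprintf("jaccard1 = %.3f from jaccard2 = %.3f; ", jaccard1, jaccard2),
         "consider a larger n3 (wider threshold separation)")
  }
  g <- grid[ok, , drop = FALSE]
  g <- g[order(g$b * g$l, g$l), , drop = FALSE]
  structure(list(b_bands = g$b[1], l_rows = g$l[1], n_hash = g$b[1] * g$l[1],
                 jaccard1 = jaccard1, jaccard2 = jaccard2,
                 p_low = p_low, p_high = p_high),
            class = "band_params")
}

#' Jaccard thresholds and band parameters with optional automatic n3
#'
#' Resolves the MinHash stage setup for a recording: with a numeric `n3`
#' it simply combines [estimate_jaccard_thresholds()] and
#' [select_band_params()]; with `n3 = "auto"` it uses the smallest `n3`
#' whose threshold pair is separable by some band setting, which always
#' exists when any is feasible (useful for sparse recordings where the
#' chance and signal similarity levels sit close together).
#'
#' @param data a [spike_data] object.
#' @param cfg a [window_config].
#' @param n3 assumed extra coincident neurons, or `"auto"`.
#' @param p_low,p_high,search_max see [select_band_params()].
#' @return List with `thresholds`, `band_params` and the resolved `n3`.
#' @export
band_setup <- function(data, cfg, n3 = 10, p_low = 0.1, p_high = 0.8,
                       search_max = 50) {
  try_one <- function(n3v) {
    thr <- estimate_jaccard_thresholds(data, cfg, n3 = n3v)
    bp <- select_band_params(thr$jaccard1, thr$jaccard2, p_low = p_low,
                             p_high = p_high, search_max = search_max)
    list(thresholds = thr, band_params = bp, n3 = n3v)
  }
  if (identical(n3, "auto")) {
    for (n3v in seq_len(data$n_neurons)) {
      res <- tryCatch(try_one(n3v), error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    stop("no n3 gives a feasible band setting for this recording")
  }
  try_one(n3)
}

#' MinHash signature matrix of activity masks
#'
#' For each of `n = b * l` random permutations of the neuron ids, each
#' window's signature entry is the minimum permuted rank over its active
#' neurons. Permutations are collision-free hashes, so two windows'
#' signature entries collide with probability equal to their Jaccard
#' similarity. Windows with no active neuron get `NA` signatures and are
#' excluded from pairing.
#'
#' @param masks logical N x M matrix from [activity_masks()].
#' @param band_params a `band_params` object (or list with `b_bands`,
#'   `l_rows`).
#' @param seed integer seed for the permutations.
#' @return An object of class `signature_matrix`: list with `S` (n x M
#'   integer matrix), `band_params`, `seed`.
#' @export
build_signatures <- function(masks, band_params, seed = 1L) {
  stopifnot(is.matrix(masks))
  n_hash <- band_params$b_bands * band_params$l_rows
  N <- nrow(masks); M <- ncol(masks)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_hash), function(q) sample.int(N), integer(N)))
  })
  act <- which(masks, arr.ind = TRUE) # (neuron, window) of active cells
  ord <- order(act[, 2])
  mask_neuron <- act[ord, 1]
  counts <- tabulate(act[, 2], nbins = M)
  mask_ptr <- as.integer(c(0L, cumsum(counts)))
  S <- cpp_minhash(mask_ptr, as.integer(mask_neuron), perms)
  structure(list(S = S, band_params = band_params, seed = seed),
            class = "signature_matrix")
}

#' Candidate window pairs by signature banding
#'
#' Splits the signature matrix into `b` bands of `l` rows; two windows form
#' a candidate pair iff their columns agree on all `l` rows of at least one
#' band. Only candidate pairs are passed on to edit-similarity scoring.
#'
#' @param sig a `signature_matrix` from [build_signatures()].
#' @param band_params band parameters (defaults to those stored in `sig`).
#' @return Two-column integer matrix of window index pairs (i < j).
#' @export
candidate_pairs <- function(sig, band_params = sig$band_params) {
  S <- sig$S
  b <- band_params$b_bands; l <- band_params$l_rows
  stopifnot(nrow(S) >= b * l)
  M <- ncol(S)
  valid <- which(!is.na(S[1, ]))
  acc <- list()
  for (band in seq_len(b)) {
    rows <- ((band - 1) * l + 1):(band * l)
    slice <- S[rows, valid, drop = FALSE]
    key <- do.call(paste, c(split(slice, row(slice)), sep = "_"))
    buckets <- split(valid, key)
    buckets <- buckets[lengths(buckets) >= 2]
    for (bk in buckets) acc[[length(acc) + 1L]] <- utils::combn(bk, 2)
  }
  if (!length(acc)) {
    return(cbind(i = integer(0), j = integer(0)))
  }
  pr <- do.call(cbind, acc)
  code <- (pr[1, ] - 1) * as.double(M) + pr[2, ]
  keep <- !duplicated(code)
  cbind(i = pr[1, keep], j = pr[2, keep])
}
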