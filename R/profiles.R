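#' Z-score window counts per neuron
#'
#' Converts spike counts to instantaneous z-scores: for each neuron the
#' mean and variance of its spike count per bin are computed over all bins
#' of the segmented data, the mean is subtracted from every bin count and
#' the difference is normalised by the variance. This suppresses the
#' influence of highly active neurons on profile construction. Neurons with
#' zero variance (silent or perfectly constant) are excluded with a
#' warning and their rows set to zero.
#'
#' @param ws a `window_set` from [segment_windows()].
#' @return A list with `get` (function(k) returning the z-scored N x L
#'   matrix of window k), `mean`, `var` (per-neuron moments) and
#'   `excluded` (neuron rows set to zero).
#' @export
zscore_windows <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  n_cells <- as.double(ws$n_windows) * ws$n_bins
  s1 <- rowsum(as.numeric(ws$spikes$count), ws$spikes$neuron)
  s2 <- rowsum(as.numeric(ws$spikes$count)^2, ws$spikes$neuron)
  mu <- numeric(ws$n_neurons)
  m2 <- numeric(ws$n_neurons)
  idx <- as.integer(rownames(s1))
  mu[idx] <- s1[, 1] / n_cells
  m2[idx] <- s2[, 1] / n_cells
  v <- m2 - mu^2
  excluded <- which(v <= 0)
  if (length(excluded)) {
    warning(length(excluded), " neuron(s) with zero spike-count variance excluded")
  }
  vs <- v
  vs[vs <= 0] <- 1
  get <- function(k) {
    W <- window_matrix(ws, k)
    Z <- (W - mu) / vs
    if (length(excluded)) Z[excluded, ] <- 0
    Z
  }
  list(get = get, mean = mu, var = v, excluded = excluded)
}

# Gaussian smoothing of a profile along the time (bin) axis, per neuron.
# sigma is in bins; the kernel is truncated at 4 sigma and renormalised.
smooth_profile <- function(P, sigma) {
  if (sigma <= 1e-9) return(P)
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  L <- ncol(P)
  out <- matrix(0, nrow(P), L)
  for (o in seq_along(x)) {
    src <- seq_len(L) - x[o]
    ok <- src >= 1 & src <= L
    out[, ok] <- out[, ok] + kern[o] * P[, src[ok]]
  }
  # renormalise by the in-range kernel mass so edges are not damped
  mass <- vapply(seq_len(L), function(j) {
    src <- j - x
    sum(kern[src >= 1 & src <= L])
  }, numeric(1))
  sweep(out, 2, mass, "/")
}

#' Consensus spatiotemporal profile of a window cluster
#'
#' Builds the cluster's core temporal structure by simplified iterative
#' multiple alignment: two arbitrary (seed-chosen) member windows
#' initialise the profile, then members are repeatedly aligned to the
#' current profile with [edit_similarity()] traceback and merged by
#' averaging the aligned bins; after every merge a Gaussian filter is
#' applied along time whose width starts at the window length and shrinks
#' geometrically to one bin, preventing the profile from containing more
#' than one copy of the sequence. Iteration stops when the edit similarity
#' between successive profiles stabilises or after `max_updates` merges.
#'
#' @param members list of z-scored N x L member matrices (>= 2), e.g.
#'   built with [zscore_windows()].
#' @param alpha gap-penalty weight used for the alignments.
#' @param max_updates maximum number of profile updates; default 20 times
#'   the number of members (within the 10x-100x range that maximises the
#'   member-profile similarity).
#' @param seed integer seed (initial pair and member visit order).
#' @param tol relative change of successive-profile similarity below which
#'   the iteration stops (after every member has been visited once).
#' @return An object of class `assembly_profile`: list with `matrix`
#'   (N x L), `trace` (successive-profile similarities), `sigma_final`,
#'   `n_updates`, `n_members`.
#' @export
build_profile <- function(members, alpha = 1, max_updates = NULL, seed = 1L,
                          tol = 1e-3) {
  stopifnot(is.list(members))
  m <- length(members)
  if (m < 2) stop("need at least 2 member windows to build a profile")
  dims <- dim(members[[1]])
  L <- dims[2]
  max_updates <- max_updates %||% (20L * m)
  # the Gaussian filter width shrinks geometrically from the window length
  # to one bin over the first 10 x m updates; convergence is only assessed
  # once the filter has reached the bin scale, so the similarity plateau
  # reflects the final smoothing level
  sched <- max(min(10L * m, max_updates), 2L)
  sigmas <- L * (1 / L)^(seq(0, 1, length.out = sched))

  with_seed(derive_seed(seed, "profile"), {
    first <- sample.int(m, 2)
    order_pool <- setdiff(seq_len(m), first)
    # A is the raw running average of aligned members; the Gaussian filter
    # is applied to the tentative profile used for alignment and reporting,
    # never to the accumulator itself (repeated smoothing of the
    # accumulator would compound across updates and blur the consensus)
    A <- (members[[first[1]]] + align_merge(members[[first[1]]],
                                            members[[first[2]]], alpha)) / 2
    P <- smooth_profile(A, sigmas[1])
    trace <- numeric(0)
    prev_sim <- NA_real_
    t <- 1L
    visit <- if (length(order_pool)) sample(order_pool) else integer(0)
    done <- FALSE
    while (t < max_updates && !done) {
      t <- t + 1L
      if (!length(visit)) visit <- sample.int(m)
      w <- members[[visit[1]]]
      visit <- visit[-1]
      aligned <- align_merge(P, w, alpha)
      A <- (t * A + aligned) / (t + 1)
      P_new <- smooth_profile(A, sigmas[min(t, length(sigmas))])
      s <- edit_similarity(P_new, P, alpha)$score
      trace <- c(trace, s)
      if (t >= sched && !is.na(prev_sim) && prev_sim > 0 &&
          abs(s - prev_sim) / prev_sim < tol) {
        done <- TRUE
      }
      prev_sim <- s
      P <- P_new
    }
  })
  structure(list(matrix = P, trace = trace,
                 sigma_final = sigmas[min(t, length(sigmas))],
                 n_updates = t, n_members = m),
            class = "assembly_profile")
}

# align member w to reference P and return w's bins rearranged onto P's
# grid: matched profile bins receive w's activity, unmatched bins receive 0
# (so in the running average unsupported bins decay toward zero)
align_merge <- function(P, w, alpha) {
  al <- edit_similarity(P, w, alpha, with_traceback = TRUE)
  out <- matrix(0, nrow(P), ncol(P))
  if (nrow(al$pairs)) out[, al$pairs[, 1]] <- w[, al$pairs[, 2]]
  out
}

#' @export
print.assembly_profile <- function(x, ...) {
  cat(sprintf("<assembly_profile> %d neurons x %d bins, %d members, %d updates\n",
              nrow(x$matrix), ncol(x$matrix), x$n_members, x$n_updates))
  invisible(x)
}

#' Edit similarity between a profile and a window
#'
#' @param profile an `assembly_profile` (or bare N x L matrix).
#' @param window numeric N x L matrix (typically z-scored).
#' @param alpha gap-penalty weight.
#' @return The edit similarity score (>= 0).
#' @export
match_profile <- function(profile, window, alpha = 1) {
  P <- if (inherits(profile, "assembly_profile")) profile$matrix else profile
  stopifnot(is.matrix(P), is.matrix(window))
  if (!all(dim(P) == dim(window))) stop("profile and window shapes differ")
  edit_similarity(P, window, alpha)$score
}

#' Neuron order by profile peak time
#'
#' Orders neurons by the bin of their maximal profile activity, the
#' presentation order used for sequence heatmaps.
#'
#' @param profile an `assembly_profile` or N x L matrix.
#' @param active_only drop neurons whose profile row is entirely <= 0.
#' @return Integer vector of neuron indices (rows), peak bins non-decreasing.
#' @export
profile_peak_order <- function(profile, active_only = TRUE) {
  P <- if (inherits(profile, "assembly_profile")) profile$matrix else profile
  peaks <- apply(P, 1, which.max)
  keep <- if (active_only) which(apply(P, 1, max) > 0) else seq_len(nrow(P))
  keep[order(peaks[keep])]
}
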