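# Brute-force edit-similarity oracle: exhaustive enumeration of all
# strictly increasing match sequences between the bins of two windows.
# Between consecutive matches a run of g skipped bins in either window
# costs exp(alpha * g); the running score is floored at zero after each
# gap charge (local restart); trailing bins are reached by charged gap
# runs (longer match sequences with zero-product matches are also
# enumerated, so the maximum is unaffected).
oracle_similarity <- function(W1, W2, alpha) {
  L <- ncol(W1)
  P <- crossprod(W1, W2)
  best <- 0
  for (m in seq_len(L)) {
    sets <- utils::combn(L, m)
    for (a in seq_len(ncol(sets))) {
      for (b in seq_len(ncol(sets))) {
        ii <- sets[, a]
        jj <- sets[, b]
        s <- 0
        for (t in seq_len(m)) {
          if (t > 1) {
            di <- ii[t] - ii[t - 1] - 1
            dj <- jj[t] - jj[t - 1] - 1
            cost <- (if (di > 0) exp(alpha * di) else 0) +
              (if (dj > 0) exp(alpha * dj) else 0)
            s <- max(0, s - cost)
          }
          s <- s + P[ii[t], jj[t]]
        }
        di <- L - ii[m]
        dj <- L - jj[m]
        cost <- (if (di > 0) exp(alpha * di) else 0) +
          (if (dj > 0) exp(alpha * dj) else 0)
        s <- max(0, s - cost)
        if (s > best) best <- s
      }
    }
  }
  best
}

# random small count window for oracle comparisons
random_small_window <- function(n_neurons, n_bins) {
  matrix(sample(0:2, n_neurons * n_bins, replace = TRUE,
                prob = c(0.6, 0.3, 0.1)),
         n_neurons, n_bins)
}
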