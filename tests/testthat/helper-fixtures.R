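# Shared fixture builders for the suite (all generated in code).

# windows holding a sequential pattern of `n_members` neurons spaced
# `spacing` bins apart with +-1 bin uniform jitter, over sparse Poisson
# background counts; returned as mean-centred matrices ready for profiling
sequential_member_windows <- function(n_windows = 20, n_neurons = 30,
                                      n_bins = 24, n_members = 10,
                                      spacing = 2, bg_rate = 0.05) {
  members <- lapply(seq_len(n_windows), function(m) {
    W <- matrix(rpois(n_neurons * n_bins, bg_rate), n_neurons, n_bins)
    start <- sample(0:(n_bins - spacing * n_members - 2), 1)
    for (a in seq_len(n_members)) {
      b <- min(max(start + spacing * a + sample(-1:1, 1), 1), n_bins)
      W[a, b] <- W[a, b] + 1
    }
    W
  })
  lapply(members, function(W) W - mean(W))
}

# two 2-D Gaussian clouds (variance 1.3) plus uniform background points,
# mapped into a similarity store via a Gaussian kernel on the distances
gaussian_cloud_store <- function(sep, n_clust = 60, n_noise = 80) {
  sdv <- sqrt(1.3)
  x <- rbind(cbind(rnorm(n_clust, -sep / 2, sdv), rnorm(n_clust, 0, sdv)),
             cbind(rnorm(n_clust, sep / 2, sdv), rnorm(n_clust, 0, sdv)),
             cbind(runif(n_noise, -8, 8), runif(n_noise, -8, 8)))
  truth <- c(rep(1L, n_clust), rep(2L, n_clust), rep(NA_integer_, n_noise))
  D <- as.matrix(dist(x))
  h <- median(D) / 4
  E <- exp(-D^2 / (2 * h^2))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  store <- similarity_store(data.frame(i = idx[, 1], j = idx[, 2],
                                       E = E[idx]), nrow(x))
  list(store = store, truth = truth, n = nrow(x))
}
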