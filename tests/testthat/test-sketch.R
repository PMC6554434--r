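test_that("activity masks flag neurons with any spike in the window", {
  sd <- spike_data(data.frame(neuron_id = c(0, 0, 0), time = c(0.12, 0.125, 0.13)),
                   n_neurons = 3, duration = 0.4)
  ws <- segment_windows(sd, window_config(0.2, 0.01))
  m <- activity_masks(ws)
  expect_equal(m[, 1], c(TRUE, FALSE, FALSE))
  expect_equal(m[, 2], rep(FALSE, 3)) # all-zero window -> all-zero mask
  # the mask only depends on which neurons fire, not when within the window
  sd2 <- spike_data(data.frame(neuron_id = c(0, 0, 0), time = c(0.01, 0.1, 0.19)),
                    n_neurons = 3, duration = 0.4)
  m2 <- activity_masks(segment_windows(sd2, window_config(0.2, 0.01)))
  expect_equal(m2[, 1], m[, 1])
})

test_that("jaccard similarity follows the set definition", {
  expect_equal(jaccard(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(jaccard(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(jaccard(c(0, 0), c(0, 0)), 0) # empty union convention
})

test_that("banding probability matches the printed series for 3 bands of 5 rows", {
  s <- c(0, 0.3, 0.5, 0.7, 0.8, 0.9, 1)
  p <- candidate_probability(s, b_bands = 3, l_rows = 5)
  expect_equal(round(p, 3), c(0, 0.007, 0.091, 0.424, 0.696, 0.931, 1))
  expect_error(candidate_probability(1.2, 3, 5), "0, 1")
})

test_that("banding probability is monotone in s, b and l", {
  s <- seq(0, 1, 0.05)
  p1 <- candidate_probability(s, 4, 6)
  expect_true(all(diff(p1) >= 0))
  expect_true(all(candidate_probability(s, 5, 6) >= p1))
  expect_true(all(candidate_probability(s, 4, 7) <= p1))
})

test_that("jaccard threshold estimates follow the Poisson closed form", {
  # homogeneous population: every neuron has the same activity probability
  # p, and jaccard1 collapses to p / (2 - p)
  set.seed(8)
  n <- 50
  ev <- data.frame(neuron_id = rep(0:(n - 1), each = 100),
                   time = runif(100 * n, 0, 100))
  sd <- spike_data(ev, n_neurons = n, duration = 100)
  cfg <- window_config(0.2, 0.01)
  thr <- estimate_jaccard_thresholds(sd, cfg, n3 = 0)
  p_i <- thr$p_active
  expect_equal(thr$jaccard1,
               sum(p_i^2) / (2 * sum(p_i) - sum(p_i^2)))
  expect_equal(thr$jaccard2, thr$jaccard1) # n3 = 0 collapses the two
  # all-equal p: jaccard1 = p/(2-p); p = 0.5 gives 1/3
  p <- 0.5
  expect_equal((n * p^2) / (2 * n * p - n * p^2), p / (2 - p))
  expect_equal(0.5 / 1.5, 1 / 3)
  # silent population
  sd0 <- spike_data(data.frame(neuron_id = 0, time = 50), n_neurons = 5,
                    duration = 100)
  thr0 <- estimate_jaccard_thresholds(sd0, cfg, n3 = 0)
  expect_lt(thr0$jaccard1, 0.01)
})

test_that("band parameter search returns a feasible, minimal setting", {
  bp <- select_band_params(0.3, 0.9)
  expect_lte(candidate_probability(0.3, bp$b_bands, bp$l_rows), 0.1)
  expect_gte(candidate_probability(0.9, bp$b_bands, bp$l_rows), 0.8)
  # the documented example setting is feasible
  expect_lte(candidate_probability(0.3, 3, 5), 0.1)
  expect_gte(candidate_probability(0.9, 3, 5), 0.8)
  # minimality: no feasible pair with a smaller signature exists
  grid <- expand.grid(b = 1:50, l = 1:50)
  ok <- candidate_probability(0.3, grid$b, grid$l) <= 0.1 &
    candidate_probability(0.9, grid$b, grid$l) >= 0.8
  expect_equal(bp$n_hash, min(grid$b[ok] * grid$l[ok]))
  # indistinguishable thresholds are rejected
  expect_error(select_band_params(0.5, 0.51), "no feasible")
  expect_error(select_band_params(0.6, 0.4), "smaller")
})

test_that("minhash signatures are permutation hashes with Jaccard collision law", {
  masks <- matrix(FALSE, 12, 4)
  masks[1:6, 1] <- TRUE
  masks[1:6, 2] <- TRUE   # identical to column 1
  masks[c(1:3, 7:9), 3] <- TRUE # Jaccard 1/3 with column 1
  bp <- list(b_bands = 3, l_rows = 4)
  sig <- build_signatures(masks, bp, seed = 5)
  expect_equal(sig$S[, 1], sig$S[, 2]) # identical masks, identical columns
  expect_true(all(is.na(sig$S[, 4]))) # empty mask -> sentinel
  # Eq: collision probability of one min-hash row equals the Jaccard
  # similarity; check with 10^4 hash functions within 3 standard errors
  n_hash <- 10000
  bp_mc <- list(b_bands = 1, l_rows = n_hash)
  sig_mc <- build_signatures(masks, bp_mc, seed = 11)
  phat <- mean(sig_mc$S[, 1] == sig_mc$S[, 3])
  j <- jaccard(masks[, 1], masks[, 3])
  se <- sqrt(j * (1 - j) / n_hash)
  expect_lt(abs(phat - j), 3 * se)
})

test_that("banded candidate pairs include identical and exclude disjoint masks", {
  masks <- matrix(FALSE, 20, 5)
  masks[1:8, 1] <- TRUE
  masks[1:8, 2] <- TRUE    # identical -> always a candidate
  masks[13:20, 3] <- TRUE  # disjoint from 1 -> never a candidate
  masks[1:7, 4] <- TRUE    # high overlap with 1
  bp <- select_band_params(0.05, 0.8)
  sig <- build_signatures(masks, bp, seed = 2)
  cp <- candidate_pairs(sig)
  key <- paste(cp[, 1], cp[, 2])
  expect_true("1 2" %in% key)
  expect_false("1 3" %in% key)
  expect_false(any(cp[, 1] == 5 | cp[, 2] == 5)) # empty mask excluded
})

test_that("pair decisions are invariant in distribution under relabelling", {
  # consistent permutation of neuron ids plus a fresh hash seed leaves the
  # candidate frequency of a fixed mask pair unchanged (within MC error)
  set.seed(3)
  masks <- matrix(FALSE, 15, 2)
  masks[1:6, 1] <- TRUE
  masks[4:9, 2] <- TRUE
  perm <- sample(15)
  masks_p <- masks[order(perm), , drop = FALSE]
  bp <- list(b_bands = 2, l_rows = 3)
  hits <- function(m, seeds) {
    mean(vapply(seeds, function(s) {
      cp <- candidate_pairs(build_signatures(m, bp, seed = s))
      nrow(cp) > 0
    }, logical(1)))
  }
  f1 <- hits(masks, 1:120)
  f2 <- hits(masks_p, 201:320)
  expect_lt(abs(f1 - f2), 0.15)
})
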