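test_that("string alignment reproduces the worked example and edge cases", {
  res <- nw_score_strings("ATCGTAC", "ATGTTAT")
  expect_equal(res$score, 5)
  expect_equal(res$subsequence, "ATGTA")

  s <- "GATTACA"
  self <- nw_score_strings(s, s)
  expect_equal(self$score, nchar(s))
  expect_equal(self$subsequence, s)

  expect_equal(nw_score_strings("A", "T")$score, 0)
  expect_equal(nw_score_strings("", "ACGT")$score, 0)
  # '#' is the null prefix and never matches
  expect_equal(nw_score_strings("#", "#")$score, 0)
})

test_that("edit similarity of a window with itself is the sum of squared bins", {
  set.seed(11)
  for (alpha in c(0.1, 1, 5)) {
    W <- matrix(rpois(60, 0.7), 5, 12)
    r <- edit_similarity(W, W, alpha, with_traceback = TRUE)
    expect_equal(r$score, sum(W^2))
    # identity alignment: the full diagonal
    expect_equal(r$pairs[, 1], r$pairs[, 2])
  }
  # two bins with single spikes score 2
  W2 <- matrix(0, 3, 4); W2[1, 2] <- 1; W2[2, 3] <- 1
  expect_equal(edit_similarity(W2, W2, 0.5)$score, 2)
})

test_that("a within-window shift keeps the full match minus one trailing gap run", {
  # pattern at bins (1,2) vs the same pattern at (2,3): the leading offset
  # is free (zero-floor restart lets the alignment begin anywhere), while
  # reaching the fixed final cell costs one gap run over the trailing
  # offset, so the score is self-similarity minus exp(alpha * offset),
  # floored at zero -- confirmed by the brute-force oracle
  W1 <- matrix(0, 4, 6); W1[1, 1] <- 1; W1[2, 2] <- 1
  W2 <- matrix(0, 4, 6); W2[1, 2] <- 1; W2[2, 3] <- 1
  for (alpha in c(0.1, 1, 3)) {
    self <- edit_similarity(W1, W1, alpha)$score
    got <- edit_similarity(W1, W2, alpha)$score
    expect_equal(got, max(0, self - exp(alpha)))
    expect_equal(got, oracle_similarity(W1, W2, alpha))
  }
  # a mismatched prefix costs nothing when the patterns line up: garbage
  # activity on other neurons before the pattern leaves the score intact
  W3 <- matrix(0, 4, 6); W3[1, 3] <- 1; W3[2, 4] <- 1
  W4 <- W3; W4[4, 1] <- 5
  expect_equal(edit_similarity(W3, W4, 1)$score,
               edit_similarity(W3, W3, 1)$score)
})

test_that("orthogonal windows score zero and shapes are checked", {
  W1 <- matrix(0, 4, 5); W1[1, ] <- 2
  W2 <- matrix(0, 4, 5); W2[2, ] <- 2
  expect_equal(edit_similarity(W1, W2, 1)$score, 0)
  expect_error(edit_similarity(matrix(0, 3, 4), matrix(0, 4, 3), 1),
               "identical dimensions")
})

test_that("score is non-increasing in alpha at a fixed internal lag", {
  # pattern at bins (2,3) vs (2,5): the second match needs an internal gap
  W1 <- matrix(0, 3, 6); W1[1, 2] <- 2; W1[2, 3] <- 2
  W2 <- matrix(0, 3, 6); W2[1, 2] <- 2; W2[2, 5] <- 2
  alphas <- c(0.05, 0.1, 0.3, 0.7, 1, 2)
  scores <- vapply(alphas, function(a) edit_similarity(W1, W2, a)$score,
                   numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  # and each value agrees with the brute-force oracle
  orc <- vapply(alphas, function(a) oracle_similarity(W1, W2, a), numeric(1))
  expect_equal(scores, orc)
})

test_that("the DP equals the brute-force oracle on small windows", {
  set.seed(42)
  for (trial in 1:120) {
    N <- sample(1:4, 1)
    L <- sample(2:6, 1)
    W1 <- random_small_window(N, L)
    W2 <- random_small_window(N, L)
    alpha <- sample(c(0.1, 0.5, 1, 2), 1)
    expect_equal(edit_similarity(W1, W2, alpha)$score,
                 oracle_similarity(W1, W2, alpha),
                 tolerance = 1e-10)
  }
})

test_that("edit similarity is symmetric and non-negative", {
  set.seed(7)
  for (trial in 1:40) {
    N <- sample(2:6, 1)
    L <- sample(3:10, 1)
    W1 <- matrix(rpois(N * L, 0.5), N, L)
    W2 <- matrix(rpois(N * L, 0.5), N, L)
    a <- runif(1, 0.05, 2)
    s12 <- edit_similarity(W1, W2, a)$score
    s21 <- edit_similarity(W2, W1, a)$score
    expect_equal(s12, s21, tolerance = 1e-10)
    expect_gte(s12, 0)
  }
})

test_that("matched bin pairs are strictly increasing in both coordinates", {
  set.seed(5)
  for (trial in 1:20) {
    W1 <- matrix(rpois(40, 0.6), 4, 10)
    W2 <- matrix(rpois(40, 0.6), 4, 10)
    p <- edit_similarity(W1, W2, 0.5, with_traceback = TRUE)$pairs
    if (nrow(p) > 1) {
      expect_true(all(diff(p[, 1]) >= 1))
      expect_true(all(diff(p[, 2]) >= 1))
    }
  }
})

test_that("batch pair scoring agrees with the dense single-pair path", {
  sd <- generate_background(20, 5, 5, seed = 3)
  ws <- segment_windows(sd, window_config(0.2, 0.01))
  pairs <- cbind(c(1, 2, 3, 7, 10), c(4, 5, 6, 9, 24))
  st <- score_candidate_pairs(ws, pairs, alpha = 0.8)
  dense <- vapply(seq_len(nrow(pairs)), function(r) {
    edit_similarity(window_matrix(ws, pairs[r, 1]),
                    window_matrix(ws, pairs[r, 2]), 0.8)$score
  }, numeric(1))
  expect_equal(st$pairs$E, dense, tolerance = 1e-12)
})

test_that("distance transform inverts similarity order and fills pruned pairs", {
  st <- similarity_store(data.frame(i = c(1, 1), j = c(2, 3), E = c(5, 2)), 4)
  ds <- distance_from_similarity(st)
  expect_equal(ds$pairs$D, c(0, 3))
  D <- as.matrix(ds)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 3)
  expect_equal(D[2, 4], 5) # never computed -> maximal distance
  expect_equal(diag(D), rep(0, 4))
  expect_true(isSymmetric(D))
  # all-equal similarities give all-zero distances on computed pairs
  st2 <- similarity_store(data.frame(i = 1:2, j = 2:3, E = c(4, 4)), 3)
  expect_equal(distance_from_similarity(st2)$pairs$D, c(0, 0))
  # argmax of E is argmin of D
  expect_equal(which.min(ds$pairs$D), which.max(st$pairs$E))
  expect_error(distance_from_similarity(
    similarity_store(data.frame(i = integer(0), j = integer(0),
                                E = numeric(0)), 3)), "empty")
})
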