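test_that("the Poisson shuffle preserves per-neuron counts exactly", {
  sd <- generate_background(20, 3, 30, seed = 1)
  sh <- poisson_shuffle(sd, seed = 2)
  expect_equal(spike_counts(sh), spike_counts(sd))
  expect_equal(sh$duration, sd$duration)
  expect_false(identical(sh$events$time, sd$events$time))
  # empty input passes through
  empty <- spike_data(data.frame(neuron_id = integer(0), time = numeric(0)),
                      n_neurons = 3, duration = 1)
  expect_equal(nrow(poisson_shuffle(empty, seed = 1)$events), 0)
})

test_that("shuffling destroys embedded structure for the detector", {
  ds <- benchmark_suite("fig6a", 1, seed = 7, duration_s = 60)[[1]]
  cfg <- ds$config
  cfg$n3 <- "auto"
  sh <- poisson_shuffle(ds$data, seed = 3)
  det <- run_pipeline(sh, cfg, profiles = FALSE)
  # on the original data the detector assigns most signal windows...
  det0 <- run_pipeline(ds$data, ds$config, profiles = FALSE)
  truth <- window_truth(ds$truth, det0$windows)
  f0 <- f_unsupervised(det0$labels, truth)$f_us
  expect_gt(f0, 0.8)
  # ...after shuffling it finds (near) nothing
  expect_lt(mean(!is.na(det$labels)), 0.25)
})

test_that("position scores separate an injected profile location", {
  set.seed(3)
  # build data whose windows at position bins 10-12 contain a sequence
  bg <- generate_background(30, 1, 60, seed = 4)
  spec <- assembly_spec(0:9, "sequential", span_s = 0.1, occurrences = 40)
  emb <- embed_assemblies(bg, spec, window_s = 0.2, seed = 5)
  cfg <- window_config(0.2, 0.01)
  ws <- segment_windows(emb$data, cfg)
  # positions: signal windows at bins 10-12, others uniform elsewhere
  tl <- window_truth(emb$truth, ws)
  bins <- ifelse(!is.na(tl), sample(10:12, ws$n_windows, replace = TRUE),
                 sample(c(1:9, 13:30), ws$n_windows, replace = TRUE))
  positions <- data.frame(time = ws$starts, position_bin = bins)
  # profile from the true member windows
  z <- zscore_windows(ws)
  members <- lapply(which(!is.na(tl))[1:15], z$get)
  prof <- build_profile(members, alpha = 1, seed = 1)
  sc <- score_by_position(prof, emb$data, positions, cfg, alpha = 1, seed = 2,
                          n_bins = 30)
  expect_s3_class(sc, "position_scores")
  expect_equal(nrow(sc), 30)
  sig_bins <- 10:12
  expect_gt(mean(sc$ed_raw[sig_bins], na.rm = TRUE),
            mean(sc$ed_raw[-sig_bins], na.rm = TRUE))
  # the shuffled surrogate shows no such elevation
  expect_lt(mean(sc$ed_sge[sig_bins], na.rm = TRUE) -
              mean(sc$ed_sge[-sig_bins], na.rm = TRUE),
            0.5 * (mean(sc$ed_raw[sig_bins], na.rm = TRUE) -
                     mean(sc$ed_raw[-sig_bins], na.rm = TRUE)))
})

test_that("the jump model recovers an injected score excess", {
  hits <- 0
  cover <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    set.seed(r)
    X <- 30
    mu <- 2 + 0.5 * sin(seq(0, pi, length.out = X)) + cumsum(rnorm(X, 0, 0.02))
    delta <- rep(0, X)
    delta[15:18] <- -2 # the original data beat the surrogate by 2 there
    raw <- rnorm(X, mu, 0.3)
    sge <- rnorm(X, mu + delta, 0.3)
    fit <- fit_jump_model(data.frame(ed_raw = raw, ed_sge = sge),
                          n_iter = 3000, n_burn = 1500, chains = 2, seed = r)
    s <- fit$summary
    hits <- hits + s$significant[15]
    cover <- cover + (s$lower[15] <= 2 && s$upper[15] >= 2)
  }
  expect_gte(hits, 0.9 * reps)
  expect_gte(cover, 0.9 * reps)
})

test_that("no effect means (almost) no flags, and exact ties never flag", {
  flags <- 0
  tot <- 0
  for (r in 1:3) {
    set.seed(100 + r)
    X <- 30
    mu <- 2 + cumsum(rnorm(X, 0, 0.05))
    raw <- rnorm(X, mu, 0.3)
    sge <- rnorm(X, mu, 0.3)
    fit <- fit_jump_model(data.frame(ed_raw = raw, ed_sge = sge),
                          n_iter = 2000, n_burn = 1000, chains = 2, seed = r)
    flags <- flags + sum(fit$summary$significant)
    tot <- tot + X
  }
  expect_lte(flags / tot, 0.07)
  # identical raw and surrogate scores: no bin can be flagged
  set.seed(9)
  same <- 2 + rnorm(30, 0, 0.2)
  fit0 <- fit_jump_model(data.frame(ed_raw = same, ed_sge = same),
                         n_iter = 2000, n_burn = 1000, chains = 2, seed = 1)
  expect_equal(sum(fit0$summary$significant), 0)
  expect_error(fit_jump_model(data.frame(ed_raw = c(1, NA, NA),
                                         ed_sge = c(1, NA, NA))),
               "at least 3")
})

test_that("missing position bins are handled as unobserved", {
  set.seed(2)
  X <- 20
  mu <- 1 + 0.1 * seq_len(X)
  raw <- rnorm(X, mu, 0.2)
  sge <- rnorm(X, mu, 0.2)
  raw[c(5, 12)] <- NA
  sge[c(5, 13)] <- NA
  fit <- fit_jump_model(data.frame(ed_raw = raw, ed_sge = sge),
                        n_iter = 1500, n_burn = 800, chains = 2, seed = 3)
  expect_equal(nrow(fit$summary), X)
  expect_true(all(is.finite(fit$summary$effect)))
  expect_true(all(fit$summary$lower <= fit$summary$upper))
})
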