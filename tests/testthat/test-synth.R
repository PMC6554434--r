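test_that("background generator matches Poisson expectations", {
  sd <- generate_background(100, 2, 300, seed = 1)
  lambda <- 100 * 2 * 300
  expect_lt(abs(nrow(sd$events) - lambda), 3 * sqrt(lambda))
  expect_equal(generate_background(5, 0, 10, seed = 1)$events,
               data.frame(neuron_id = integer(0), time = numeric(0)))
  # reproducibility, byte for byte
  expect_identical(generate_background(20, 3, 30, seed = 7),
                   generate_background(20, 3, 30, seed = 7))
})

test_that("inter-spike intervals are exponential for most neurons", {
  sd <- generate_background(100, 2, 300, seed = 5)
  pvals <- vapply(0:99, function(i) {
    t <- sort(sd$events$time[sd$events$neuron_id == i])
    isi <- diff(t)
    # ties from finite time resolution provoke a harmless ks.test warning
    suppressWarnings(
      stats::ks.test(isi, "pexp", rate = 1 / mean(isi))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("embedded occurrences respect membership, count and boundaries", {
  bg <- generate_background(100, 2, 100, seed = 2)
  specs <- lapply(1:5, function(k) {
    assembly_spec(((k - 1) * 20):(k * 20 - 1), "synchronous",
                  jitter_s = 0.01, occurrences = 17)
  })
  emb <- embed_assemblies(bg, specs, window_s = 0.2, seed = 3)
  occ <- emb$truth$occurrences
  expect_equal(nrow(occ), 5 * 17)
  expect_equal(as.vector(table(occ$assembly)), rep(17, 5))
  # no occurrence crosses its window boundary
  expect_true(all(occ$start >= (occ$window - 1) * 0.2))
  expect_true(all(occ$end < occ$window * 0.2))
  # members also keep their background spikes
  expect_gt(sum(emb$data$events$neuron_id == 0),
            sum(occ$assembly == 1) + 0) # background adds extra spikes
  expect_equal(nrow(emb$data$events), nrow(bg$events) + 5 * 17 * 20)
  # impossible placements error out
  expect_error(embed_assemblies(bg, list(assembly_spec(0:1, occurrences = 9999)),
                                window_s = 0.2, seed = 1), "cannot place")
  expect_error(embed_assemblies(bg, list(assembly_spec(200:205)),
                                window_s = 0.2), "outside the population")
})

test_that("sequential mode orders members over the span, reverse reverses it", {
  bg <- generate_background(20, 0.1, 50, seed = 4)
  fwd <- embed_assemblies(bg, list(assembly_spec(0:9, "sequential",
                                                 span_s = 0.1,
                                                 occurrences = 1)),
                          window_s = 0.2, seed = 5)
  sp <- fwd$data$events
  tt <- sp$time[order(sp$time)]
  occ <- fwd$truth$occurrences
  inside <- sp[sp$time >= occ$start & sp$time <= occ$end &
                 sp$neuron_id < 10, ]
  expect_equal(inside$neuron_id[order(inside$time)], 0:9)
  rev_ <- embed_assemblies(bg, list(assembly_spec(0:9, "sequential-reverse",
                                                  span_s = 0.1,
                                                  occurrences = 1)),
                           window_s = 0.2, seed = 5)
  ins2 <- rev_$data$events
  ins2 <- ins2[ins2$time >= rev_$truth$occurrences$start &
                 ins2$time <= rev_$truth$occurrences$end &
                 ins2$neuron_id < 10, ]
  expect_equal(ins2$neuron_id[order(ins2$time)], 9:0)
  # compression shortens the emitted span
  comp <- embed_assemblies(bg, list(assembly_spec(0:9, "sequential",
                                                  span_s = 0.1,
                                                  occurrences = 5,
                                                  time_scale = 5)),
                           window_s = 0.2, seed = 6)
  spans <- comp$truth$occurrences$end - comp$truth$occurrences$start
  expect_true(all(spans <= 0.1 / 5 + 1e-9))
})

test_that("benchmark regimes have the documented composition", {
  ds <- benchmark_suite("fig6a", 1, seed = 1)[[1]]
  expect_equal(ds$data$n_neurons, 100)
  expect_equal(ds$data$duration, 300)
  expect_equal(nrow(ds$truth$occurrences), 250) # 5 assemblies x 50
  expect_equal(length(ds$truth$specs), 5)
  expect_true(all(vapply(ds$truth$specs,
                         function(s) length(s$members), integer(1)) == 20))
  ws <- segment_windows(ds$data, window_config(0.2, 0.01))
  expect_equal(sum(!is.na(window_truth(ds$truth, ws))), 250)

  d35 <- benchmark_suite("sec3_5_100ms", 1, seed = 1)[[1]]
  expect_equal(d35$data$n_neurons, 100)
  expect_equal(d35$data$duration, 60)
  expect_equal(nrow(d35$truth$occurrences), 60)
  expect_equal(length(d35$truth$specs[[1]]$members), 10)

  dg <- benchmark_suite("fig6g", 1, seed = 1)[[1]]
  expect_equal(vapply(dg$truth$specs, function(s) s$time_scale, numeric(1)),
               c(1, 3, 5, 10))
  expect_equal(nrow(dg$truth$occurrences), 80)

  expect_error(benchmark_suite("nope", 1), "unknown regime")
  # distinct datasets from one master seed; identical on repeat
  two <- benchmark_suite("fig4", 2, seed = 9)
  expect_false(identical(two[[1]]$data$events, two[[2]]$data$events))
  again <- benchmark_suite("fig4", 2, seed = 9)
  expect_identical(two[[1]]$data$events, again[[1]]$data$events)
})
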