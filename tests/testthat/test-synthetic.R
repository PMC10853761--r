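test_that("synthetic EIs have the prescribed peak and axonal latency order", {
  arr <- build_grid_geometry(8, 8, 60)
  spec <- synthetic_neuron_spec(c(60, 180), rbind(c(60, 180), c(420, 180)),
                                peak_amplitude = 30, decay_length = 50)
  ei <- gen_synthetic_ei(arr, spec, T = 71)
  expect_s3_class(ei, "electrical_image")
  expect_equal(max(abs(ei$voltages)), 30)
  expect_equal(ei$peak_amplitude, 30)
  # electrodes sitting on the axon at increasing arc-length: trough later
  path_ids <- vapply(c(60, 180, 300, 420), function(x)
    arr$ids[arr$x == x & arr$y == 180], integer(1))
  troughs <- apply(ei$voltages[path_ids + 1, ], 1, which.min)
  expect_true(all(diff(troughs) > 0))
  # deterministic
  expect_identical(ei, gen_synthetic_ei(arr, spec, T = 71))
  expect_error(gen_synthetic_ei(arr, spec, T = 12), "too small")
})

test_that("artifact ground truth decays radially and scales linearly", {
  arr <- build_grid_geometry(8, 8, 60)
  stim <- 27L
  M <- gen_artifact_truth(arr, stim, T = 55, decay_length = 100)
  expect_equal(dim(M), c(64, 55))
  expect_true(all(M[, 1] == 0))        # first post-stimulus sample is baseline
  # the stimulating electrode carries the largest trace
  peaks <- apply(abs(M), 1, max)
  expect_equal(which.max(peaks) - 1L, stim)
  # amplitude decays monotonically with distance from the stimulation site
  p0 <- cbind(arr$x, arr$y)[stim + 1, ]
  d0 <- sqrt((arr$x - p0[1])^2 + (arr$y - p0[2])^2)
  expect_true(all(diff(peaks[order(d0)]) <= 1e-9))
  # slow-tail ratio across two electrodes follows the slow spatial decay
  p <- cbind(arr$x, arr$y)[stim + 1, ]
  d <- sqrt((arr$x - p[1])^2 + (arr$y - p[2])^2)
  e1 <- which(d == 60)[1] - 1L; e2 <- which(d == 120)[1] - 1L
  t_tail <- 50                          # fast component long gone
  ratio <- M[e2 + 1, t_tail] / M[e1 + 1, t_tail]
  expect_equal(ratio, exp(-(120 - 60) / (1.5 * 100)), tolerance = 1e-3)
  expect_error(gen_artifact_truth(arr, 999L, T = 55), "unknown electrode")
})

test_that("amplitude grids are log-spaced with exact endpoints", {
  q <- gen_amplitude_grid(39, 0.1, 4.1)
  expect_length(q, 39)
  expect_identical(q[1], 0.1)
  expect_identical(q[39], 4.1)
  expect_true(all(diff(q) > 0))
  expect_equal(diff(log(q)), rep(log(4.1 / 0.1) / 38, 38), tolerance = 1e-12)
  expect_equal(gen_amplitude_grid(2, 1, 10), c(1, 10))
  expect_equal(gen_amplitude_grid(3, 1, 100), c(1, 10, 100))
  expect_error(gen_amplitude_grid(10, 0, 1), "lo")
})

test_that("the stimulus waveform is triphasic and charge balanced", {
  w <- gen_stim_waveform(3, stim_protocol())
  expect_equal(unique(w), c(2, -3, 1))
  expect_lt(abs(sum(w)), 1e-12)
  w2 <- gen_stim_waveform(4.1, stim_protocol())
  expect_equal(w2[length(w2) / 3 + 1], -4.1)
  expect_equal(w2[1], 2 * 4.1 / 3, tolerance = 1e-12)
  expect_lt(abs(sum(gen_stim_waveform(1.234, stim_protocol()))), 1e-12)
})

test_that("protocol validation enforces ordering and charge balance", {
  expect_error(stim_protocol(c(1, 1, 2)), "increasing")
  expect_error(stim_protocol(repeats = 0), "repeats")
  expect_error(stim_protocol(phase_ratios = c(2, -3, 2)), "charge")
})

test_that("spike-free noiseless trials equal the scaled unit artifact", {
  arr <- build_grid_geometry(5, 5, 60)
  M <- gen_artifact_truth(arr, 12L, T = 30)
  proto <- stim_protocol(c(0.5, 1, 2), repeats = 2)
  empty_truth <- ground_truth(data.frame(neuron_id = integer(0),
                                         q50_uA = numeric(0),
                                         slope = numeric(0)))
  ds <- gen_stim_dataset(arr, list(), M, proto, empty_truth,
                         noise = noise_model(0), stim_electrode = 12L,
                         T = 30, seed = 5)
  expect_equal(dim(ds$recording$data)[1], 6)
  for (tr in 1:6)
    expect_equal(t(ds$recording$data[tr, , ]),
                 ds$recording$amplitudes[tr] * M, tolerance = 1e-12)
  expect_equal(nrow(ds$truth$spikes), 0)
})

test_that("dataset generation is seed-reproducible and respects the protocol", {
  fx <- small_fixture()
  proto <- stim_protocol(gen_amplitude_grid(5, 0.5, 2), repeats = 4)
  truth <- ground_truth(data.frame(neuron_id = 0:3, q50_uA = c(1, 1, Inf, Inf),
                                   slope = 0.1))
  args <- list(fx$array, fx$eis, fx$artifact_truth, proto, truth,
               noise = noise_model(1), stim_electrode = fx$stim_electrode,
               T = 55, seed = 7)
  ds1 <- do.call(gen_stim_dataset, args)
  ds2 <- do.call(gen_stim_dataset, args)
  expect_identical(ds1$recording$data, ds2$recording$data)
  expect_identical(ds1$truth$spikes, ds2$truth$spikes)
  expect_equal(dim(ds1$recording$data)[1], 20)
  # neurons with infinite threshold never fire
  expect_false(any(ds1$truth$spikes$neuron_id %in% c(2, 3)))
  # realised latencies stay inside the requested range
  expect_true(all(ds1$truth$spikes$latency_samples %in% 8:12))
  expect_error(do.call(gen_stim_dataset,
                       c(args[-9], list(latency_range = c(50, 60)))),
               "window")
})

test_that("empirical activation frequency matches the logistic truth", {
  arr <- build_grid_geometry(3, 3, 60)
  spec <- synthetic_neuron_spec(c(60, 60), peak_amplitude = 50)
  ei <- gen_synthetic_ei(arr, spec, T = 40, neuron_id = 0L)
  proto <- stim_protocol(c(0.8, 1.0, 1.25), repeats = 600)
  truth <- ground_truth(data.frame(neuron_id = 0L, q50_uA = 1, slope = 0.15))
  ds <- gen_stim_dataset(arr, list(ei), NULL, proto, truth,
                         noise = noise_model(0), stim_electrode = 4L,
                         T = 40, seed = 11)
  for (q in proto$amplitudes) {
    trials <- which(ds$recording$amplitudes == q)
    k <- sum(ds$truth$spikes$trial %in% trials)
    p <- activation_probability(q, 1, 0.15)
    expect_lt(abs(k / 600 - p), 3 * sqrt(p * (1 - p) / 600))
  }
})
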