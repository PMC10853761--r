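test_that("input-space similarity is shift-seeking and bounded", {
  tmpl <- input_template(rbind(c(0, 1, rep(0, 18)),
                               c(0, 0, 0, 0, 1, rep(0, 15))),
                         c(1L, 4L), "ei")
  # identity
  s <- similarity(tmpl$pulses, tmpl, latency_range = 0:10)
  expect_equal(s$score, 1)
  expect_equal(s$latency, 0L)
  # pure shift
  shifted <- cbind(matrix(0, 2, 5), tmpl$pulses[, 1:15])
  s5 <- similarity(shifted, tmpl, latency_range = 0:10)
  expect_equal(s5$score, 1)
  expect_equal(s5$latency, 5L)
  # zero and negligible estimates score 0 by convention
  expect_equal(similarity(matrix(0, 2, 20), tmpl)$score, 0)
  expect_equal(similarity(matrix(1e-9, 2, 20), tmpl)$score, 0)
  expect_error(similarity(tmpl$pulses, tmpl, latency_range = integer(0)),
               "non-empty")
})

test_that("response-space similarity scores a perfect estimate at 1", {
  fx <- small_fixture()
  mod <- fx$ei_models[[1]]
  T <- fx$T_rec
  u <- matrix(0, 2, T)
  u[cbind(1:2, mod$template$pulse_times + 9L + 1L)] <- 1
  s <- similarity_response(u, mod, latency_range = 0:20)
  expect_equal(s$score, 1, tolerance = 1e-9)
  expect_equal(s$latency, 9L)
  # an estimate at half the template amplitude is attenuated by the gate
  s_half <- similarity_response(0.4 * u, mod, latency_range = 0:20)
  expect_lt(s_half$score, s$score)
})

test_that("raising the detection threshold never adds detections", {
  fx <- small_fixture()
  agg <- fx$agg
  T <- fx$T_rec
  u_a <- artifact_inputs(agg$models[[length(agg$models)]]$template, 1, T)
  set.seed(3)
  u <- template_inputs(agg, stats::setNames(c(9L, 11L), c(0L, 2L)), T)
  y <- simulate_aggregate(agg, u, u_a) + matrix(rnorm(36 * T, sd = 2), 36)
  est <- estimate_inputs(y, agg, u_a, lambda = 1e-2)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.99), function(th)
    sum(detect(est, agg, threshold = th)$detected), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the enumeration oracle recovers noiseless spikes exactly", {
  fx <- small_fixture()
  agg <- fx$agg
  T <- fx$T_rec
  u_a <- artifact_inputs(agg$models[[length(agg$models)]]$template, 1.5, T)
  u <- template_inputs(agg, stats::setNames(10L, 1L), T)
  y <- simulate_aggregate(agg, u, u_a)
  orc <- oracle_enumerate(y, agg, u_a, latency_range = 8:12)
  expect_equal(orc$neuron_ids, 1L)
  expect_equal(unname(orc$latencies), 10L)
  # artifact-only data: the empty hypothesis wins
  y0 <- simulate_aggregate(agg, NULL, u_a)
  orc0 <- oracle_enumerate(y0, agg, u_a, latency_range = 8:12)
  expect_length(orc0$neuron_ids, 0)
})

test_that("detector and oracle agree on noisy and noiseless fixtures", {
  oa0 <- oracle_agreement_study(seed = 4, n_trials = 15, noise_std = 0)
  expect_equal(oa0$agreement, 1)
  oa <- oracle_agreement_study(seed = 4, n_trials = 40, noise_std = 1)
  expect_gte(oa$agreement, 0.95)
})

test_that("detected latencies fall inside the generator's range", {
  fx <- small_fixture()
  agg <- fx$agg
  T <- fx$T_rec
  u_a <- artifact_inputs(agg$models[[length(agg$models)]]$template, 1, T)
  set.seed(5)
  for (lat in c(8L, 10L, 12L)) {
    u <- template_inputs(agg, stats::setNames(lat, 0L), T)
    y <- simulate_aggregate(agg, u, u_a) + matrix(rnorm(36 * T, sd = 1), 36)
    est <- estimate_inputs(y, agg, u_a, lambda = 1e-2)
    d <- detect(est, agg)
    expect_true(d$latency_samples[d$neuron_id == 0] %in% 6:14)
  }
})

test_that("sorting accuracy compares called and true neuron sets per trial", {
  calls <- data.frame(trial = rep(1:3, each = 2),
                      neuron_id = rep(c(0L, 1L), 3),
                      detected = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  truth <- data.frame(trial = c(1L, 2L, 2L), neuron_id = c(0L, 0L, 1L))
  res <- sorting_accuracy(calls, truth)
  expect_equal(res$accuracy, 1)        # all three trials called correctly
  expect_equal(res$per_neuron$precision, c(1, 1))
  expect_equal(res$per_neuron$recall, c(1, 1))
  # all-miss calls against all-spiking truth
  calls$detected <- FALSE
  expect_equal(sorting_accuracy(calls, truth)$accuracy, 1 / 3)
  truth_bad <- rbind(truth, data.frame(trial = 9L, neuron_id = 0L))
  expect_error(sorting_accuracy(calls, truth_bad), "absent")
})
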