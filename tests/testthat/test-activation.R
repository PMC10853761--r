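make_calls <- function(amps, k, n = 25, neuron_id = 0L) {
  do.call(rbind, lapply(seq_along(amps), function(i) {
    data.frame(trial = seq_len(n) + (i - 1) * n, neuron_id = neuron_id,
               amplitude_uA = amps[i],
               detected = seq_len(n) <= k[i])
  }))
}

test_that("activation curves conserve the empirical counts", {
  amps <- gen_amplitude_grid(5, 0.5, 2)
  calls <- make_calls(amps, k = c(0, 2, 10, 20, 25))
  cv <- build_activation_curve(calls, 0L, stim_electrode = 7L)
  expect_equal(cv$probabilities, c(0, 2, 10, 20, 25) / 25)
  expect_equal(cv$probabilities[3], 0.4)
  expect_equal(cv$trial_counts, rep(25, 5))
  expect_error(build_activation_curve(calls, 5L), "no calls")
})

test_that("sigmoid fitting recovers thresholds and flags degeneracy", {
  amps <- gen_amplitude_grid(39, 0.1, 4.1)
  # perfect step: q50 lands between the bracketing amplitudes
  qstar <- amps[20]
  k <- ifelse(amps > qstar, 25, 0)
  fit <- fit_sigmoid(build_activation_curve(make_calls(amps, k), 0L))
  expect_true(fit$converged)
  expect_gte(fit$q50, amps[20])
  expect_lte(fit$q50, amps[21])
  # symmetric counts around an amplitude with p = 0.5 recover it exactly
  amps3 <- c(0.5, 1, 2)
  fit3 <- fit_sigmoid(build_activation_curve(make_calls(amps3, c(5, 13, 21), n = 26), 0L))
  expect_equal(fit3$q50, 1, tolerance = 1e-6)
  # degenerate curves are flagged, not errors
  expect_false(fit_sigmoid(build_activation_curve(make_calls(amps3, c(0, 0, 0)), 0L))$converged)
  expect_false(fit_sigmoid(build_activation_curve(make_calls(amps3, c(25, 25, 25)), 0L))$converged)
})

test_that("Bernoulli draws from a known logistic recover q50 within 10%", {
  amps <- gen_amplitude_grid(39, 0.1, 4.1)
  set.seed(21)
  p <- activation_probability(amps, q50 = 1, slope = 0.1)
  k <- rbinom(length(amps), 25, p)
  fit <- fit_sigmoid(build_activation_curve(make_calls(amps, k), 0L))
  expect_true(fit$converged)
  expect_lt(abs(fit$q50 - 1), 0.1)
  # invariance to amplitude ordering
  ord <- sample(length(amps))
  calls <- make_calls(amps[ord], k[ord])
  fit2 <- fit_sigmoid(build_activation_curve(calls, 0L))
  expect_equal(fit2$q50, fit$q50, tolerance = 1e-9)
})

test_that("K-fold splits are stratified, disjoint and covering", {
  rec <- recording(array(0, c(100, 4, 3)), rep(gen_amplitude_grid(4, 0.5, 2), each = 25),
                   stim_electrode = 0L)
  folds <- kfold_split(rec, K = 5, seed = 2)
  expect_length(folds, 5)
  for (f in folds)
    for (q in unique(rec$amplitudes))
      expect_equal(sum(rec$amplitudes[f] == q), 5)
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, 1:100)
  expect_equal(sum(duplicated(unlist(folds))), 0)
  # leave-one-out per amplitude
  loo <- kfold_split(rec, K = 25, seed = 2)
  expect_true(all(vapply(loo, length, integer(1)) == 4))
  expect_error(kfold_split(rec, K = 26), "fewer than K")
})

test_that("threshold comparison matches hand-computed Pearson R^2", {
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  cmp <- compare_thresholds(a, b)
  expect_equal(cmp$r2, 27 / 28)
  expect_equal(compare_thresholds(a, a)$r2, 1)
  expect_equal(compare_thresholds(a, a)$r2_identity, 1)
  # Pearson R^2 ignores a constant offset; the identity-line R^2 does not
  off <- compare_thresholds(a, a + 1)
  expect_equal(off$r2, 1)
  expect_lt(off$r2_identity, 1)
  # undefined pairs are excluded and counted
  cmp_na <- compare_thresholds(c(a, 5), c(b, NA))
  expect_equal(cmp_na$n_pairs, 3)
  expect_equal(cmp_na$n_excluded, 1)
  expect_error(compare_thresholds(1, 2), "2 matched pairs")
  expect_error(compare_thresholds(c(1, 1), c(2, 3)), "variance")
})

test_that("K-fold validation covers every trial once and is stable when noiseless", {
  fx <- small_fixture()
  proto <- stim_protocol(gen_amplitude_grid(6, 0.3, 3), repeats = 6)
  truth <- ground_truth(data.frame(neuron_id = 0:3,
                                   q50_uA = c(0.6, 1, 1.6, Inf), slope = 0.1))
  ds <- gen_stim_dataset(fx$array, fx$eis, fx$artifact_truth, proto, truth,
                         noise = noise_model(0), stim_electrode = fx$stim_electrode,
                         T = fx$T_rec, seed = 3)
  kf <- kfold_activation(ds$recording, fx$array, fx$ei_models, K = 2,
                         seed = 1, radius = Inf, fit_frac = 0.35, trim = 0)
  expect_equal(sort(unique(kf$calls$trial)), seq_len(36))
  expect_equal(nrow(kf$calls), 36 * 4)
  # every probability is a count ratio over the pooled trials
  cv <- kf$pooled_curves[["0"]]
  expect_equal(cv$probabilities * cv$trial_counts, cv$spike_counts)
})
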