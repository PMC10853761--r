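test_that("relevant-electrode selection follows the peak thresholds", {
  fx <- small_fixture()
  ei <- fx$eis[[1]]
  peaks <- apply(abs(ei$voltages), 1, max)
  # fraction 1: only the global-peak electrode(s)
  top <- select_relevant_electrodes(ei, frac_threshold = 1)
  expect_true((which.max(peaks) - 1L) %in% top)
  expect_true(all(peaks[top + 1] == max(peaks)))
  # both thresholds zero: every electrode with any signal
  all_sig <- select_relevant_electrodes(ei, 0, 0)
  expect_equal(all_sig, sort(which(peaks > 0) - 1L))
  expect_error(select_relevant_electrodes(
    electrical_image(0L, matrix(0, 3, 5))), "zero")
})

test_that("selection radius matches the exponential-decay inversion", {
  arr <- build_grid_geometry(10, 10, 60)
  dl <- 55
  spec <- synthetic_neuron_spec(c(120, 240), rbind(c(120, 240), c(420, 240)),
                                peak_amplitude = 80, decay_length = dl)
  ei <- gen_synthetic_ei(arr, spec, T = 71)
  frac <- 0.1
  sel <- select_relevant_electrodes(ei, frac_threshold = frac)
  # electrodes qualify iff within dl * ln(1/frac) of the axon path
  dp <- dynsort:::densify_path(spec$axon_path)
  d <- vapply(seq_len(100), function(e)
    sqrt(min((dp$pts[, 1] - arr$x[e])^2 + (dp$pts[, 2] - arr$y[e])^2)),
    numeric(1))
  expect_setequal(sel, which(d <= dl * log(1 / frac) + 1e-9) - 1L)
})

test_that("template pulses trigger the falling and rising phases", {
  ei <- toy_biphasic_ei()
  tmpl <- design_ei_template(ei)
  # fall pulse at the last quiet sample before the trace leaves baseline,
  # rise pulse at the trough where repolarisation begins
  expect_equal(tmpl$pulse_times, c(0L, 2L))
  expect_true(all(abs(tmpl$pulses[tmpl$pulses != 0]) == 1))
  expect_equal(sum(tmpl$pulses != 0), 2)
  # translation equivariance
  shifted <- electrical_image(0L, cbind(matrix(0, 2, 3), ei$voltages))
  tmpl_s <- design_ei_template(shifted)
  expect_equal(tmpl_s$pulse_times, tmpl$pulse_times + 3L)
  expect_error(design_ei_template(electrical_image(0L, rbind(1:9, 0))),
               "monotone")
})

test_that("data from a known stable model refits exactly", {
  for (seed in c(3, 17)) {
    mod <- random_lds(seed, m = 5, E = 30, T_u = 60, pulse_times = c(5L, 11L))
    y <- simulate_lds(mod, mod$template$pulses)
    ei <- electrical_image(0L, y)
    refit <- fit_ei_model(ei, mod$electrode_subset, mod$template, ridge = 0)
    err <- snrmse(ei, simulate_lds(refit, mod$template$pulses),
                  mod$electrode_subset)
    expect_lt(err, 1e-8)
    # output stays exactly zero off the subset
    pred <- simulate_lds(refit, mod$template$pulses)
    outside <- setdiff(0:29, mod$electrode_subset)
    expect_true(all(pred[outside + 1, ] == 0))
  }
})

test_that("fitting rejects empty signals and misaligned templates", {
  v <- matrix(0, 3, 12)
  v[1, ] <- c(0, -1, -2, -1, 0, 1, 2, 1, 0, 0, 0, 0)
  ei <- electrical_image(0L, v)
  expect_error(fit_ei_model(ei, subset = c(1L, 2L)), "zero")
  tmpl_short <- input_template(matrix(c(1, 0, 0, 0, 0, 1), 2), c(0L, 2L), "ei")
  expect_error(fit_ei_model(ei, template = tmpl_short), "aligned")
})

test_that("synthetic EIs are reproduced with low normalised error", {
  fx <- small_fixture()
  errs <- vapply(fx$ei_models, function(m) m$fit$snrmse, numeric(1))
  expect_true(all(errs < 0.5))
  expect_true(all(vapply(fx$ei_models, function(m) m$spectral_radius,
                         numeric(1)) <= 1))
})

test_that("snrmse matches hand-computed values", {
  ei <- electrical_image(0L, rbind(c(3, 4), c(0, 0)))
  expect_equal(snrmse(ei, matrix(0, 2, 2), subset = 0L), 1)
  expect_equal(snrmse(ei, rbind(c(3, 0), c(0, 0)), subset = 0L), 4 / 5)
  expect_equal(snrmse(ei, ei$voltages, subset = 0L), 0)
  expect_error(snrmse(ei, matrix(0, 2, 2), subset = 1L), "zero RMS")
  expect_error(snrmse(ei, matrix(0, 3, 3), subset = 0L), "shape")
})
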