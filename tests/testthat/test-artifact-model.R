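make_rec <- function(mats, amps, stim = 0L) {
  # mats: list of E x T trial matrices
  E <- nrow(mats[[1]]); T <- ncol(mats[[1]])
  dat <- array(0, c(length(mats), T, E))
  for (i in seq_along(mats)) dat[i, , ] <- t(mats[[i]])
  recording(dat, amps, stim)
}

test_that("trial averaging applies the trimmed-mean convention", {
  E <- 2; T <- 3
  m0 <- matrix(0, E, T); m10 <- matrix(10, E, T); m100 <- matrix(100, E, T)
  rec <- make_rec(list(m0, m10), c(1, 1))
  expect_equal(average_trials(rec, 1, trim = 0), matrix(5, E, T))
  rec4 <- make_rec(list(m0, m0, m0, m100), c(2, 2, 2, 2))
  expect_equal(average_trials(rec4, 2, trim = 0.25), matrix(0, E, T))
  # identical trials average to the trial itself
  rec2 <- make_rec(list(m10, m10, m10), c(1, 1, 1))
  expect_equal(average_trials(rec2, 1), m10)
  expect_error(average_trials(rec, 3), "no trials")
  expect_error(average_trials(rec, 1, trim = 0.7), "trim")
})

test_that("artifact state electrodes exclude the stimulation site", {
  arr <- build_grid_geometry(5, 5, 60)
  stim <- 12L  # interior
  sel <- select_artifact_electrodes(arr, stim, radius = 60)
  expect_length(sel, 4)                       # the 4 axial neighbours
  expect_false(stim %in% sel)
  all_but <- select_artifact_electrodes(arr, stim, radius = Inf)
  expect_setequal(all_but, setdiff(arr$ids, stim))
  expect_error(select_artifact_electrodes(arr, stim, radius = 0), "radius")
  expect_error(select_artifact_electrodes(arr, stim, radius = 10), "no electrodes")
})

test_that("the artifact template has three unit onset pulses", {
  averaged <- list(matrix(1, 4, 20), matrix(2, 4, 20))
  tmpl <- fit_artifact_template(averaged)
  expect_equal(nrow(tmpl$pulses), 3)
  expect_equal(tmpl$pulse_times, 0:2)
  # disjoint single-sample supports
  expect_equal(colSums(tmpl$pulses != 0)[1:3], c(1, 1, 1),
               ignore_attr = TRUE)
  expect_true(all(tmpl$pulses[, -(1:3)] == 0))
  # amplitude independence
  expect_identical(tmpl, fit_artifact_template(lapply(averaged, `*`, 3)))
  expect_error(fit_artifact_template(averaged[1]), "2 amplitudes")
  expect_error(fit_artifact_template(list(matrix(1, 4, 3), matrix(1, 4, 3))),
               "onset")
})

test_that("artifact data from a known model refits exactly and scales with q", {
  rt <- identification_roundtrip(seed = 5)
  expect_true(all(rt$artifact_anrmse < 1e-8))
  expect_lt(rt$linearity_err, 1e-12)
})

test_that("the low-rank artifact truth is realised almost exactly", {
  arr <- build_grid_geometry(5, 5, 60)
  stim <- 12L
  M <- gen_artifact_truth(arr, stim, T = 30)
  subset <- select_artifact_electrodes(arr, stim, radius = 100)
  amps <- c(0.5, 1, 2)
  averaged <- lapply(amps, function(q) q * M)
  # two spatiotemporal modes: the modal realisation captures them exactly
  fit <- fit_artifact_model(averaged, amps, subset, stim, ridge = 0)
  expect_lt(max(fit$fit$anrmse$anrmse), 1e-6)
  # never a state, never fit: the stimulating electrode
  expect_error(fit_artifact_model(averaged, amps, c(stim, subset), stim),
               "stimulating")
  # zero signal is a hard error
  expect_error(fit_artifact_model(lapply(averaged, `*`, 0), amps, subset,
                                  stim),
               "zero")
})

test_that("anrmse matches hand-computed values", {
  meas <- rbind(c(1, 1), 0)
  expect_equal(anrmse(meas, matrix(0, 2, 2), subset = 0L), 1)
  expect_equal(anrmse(meas, rbind(c(0, 2), 0), subset = 0L), 1)
  expect_equal(anrmse(meas, meas, subset = 0L), 0)
  expect_error(anrmse(matrix(0, 2, 2), matrix(0, 2, 2), 0L), "zero RMS")
})

test_that("ANRMSE decreases with stimulation amplitude under a fixed noise floor", {
  tr <- anrmse_trend_study(seed = 2, rows = 8, cols = 8,
                           protocol = stim_protocol(gen_amplitude_grid(10, 0.1, 4.1),
                                                    repeats = 8))
  expect_lt(attr(tr, "spearman"), 0)
  expect_gt(tr$anrmse[1], tr$anrmse[nrow(tr)])
})
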