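test_that("window operators expand the recursion correctly", {
  # diagonal 2-state model: the forced-response blocks are C A^{k-1-j} B
  # with a zero block row at k = 0 (no direct feedthrough)
  a <- c(0.7, 0.4); b <- c(1.3, -0.8)
  tmpl <- input_template(rbind(c(1, rep(0, 19)), c(0, 1, rep(0, 18))),
                         c(0L, 1L), "ei")
  mod <- state_space_model(diag(a), diag(b), c(0L, 2L), tmpl,
                           "ei", 0L, n_electrodes = 3)
  agg <- assemble(list(mod))
  op <- build_window_operator(agg, L = 1)
  expect_equal(dim(op$Phi), c(6, 2))          # (L+1) * 3 electrodes x m
  # no direct feedthrough: the k = 0 block of G is zero
  expect_true(all(op$G[1:3, ] == 0))
  # k = 1 block of the current-step columns is C B on the driven rows
  expect_equal(op$G[4:6, 1], c(b[1], 0, 0))
  expect_equal(op$G[4:6, 2], c(0, 0, b[2]))
  expect_equal(op$Phi[, 1], c(1, 0, 0, a[1], 0, 0))
  # longer window: forced response follows C A^{k-1} B on the driven row
  op3 <- build_window_operator(agg, L = 3)
  expect_equal(op3$G[3 * (1:3) + 1, 1], b[1] * a[1]^(0:2))
})

test_that("exact noiseless recovery holds for 1-3 firing neurons", {
  fx <- small_fixture()
  for (k in 1:3) {
    r <- recovery_experiment(fx, 0:(k - 1), lambda = 0)
    expect_lt(max(r$rmse$rmse), 1e-6)
    expect_setequal(r$calls$neuron_id[r$calls$detected], 0:(k - 1))
  }
})

test_that("artifact-only trials yield a null input estimate", {
  fx <- small_fixture()
  r <- recovery_experiment(fx, integer(0), q = 2, lambda = 0)
  expect_lt(max(abs(r$estimate$u_hat)), 1e-6)
  expect_false(any(r$calls$detected))
})

test_that("excluding rank-preserving electrodes leaves recovery exact", {
  fx <- small_fixture()
  base <- recovery_experiment(fx, 0:2, lambda = 0)
  excl <- recovery_experiment(fx, 0:2, lambda = 0, excluded = "stim")
  expect_identical(base$calls$detected, excl$calls$detected)
  expect_lt(max(excl$rmse$rmse), 1e-6)
  # an electrode outside every subset is irrelevant
  used <- sort(unique(unlist(lapply(fx$agg$models, `[[`, "electrode_subset"))))
  free <- setdiff(fx$array$ids, used)
  if (length(free) > 0) {
    alt <- recovery_experiment(fx, 0:2, lambda = 0, excluded = free[1])
    expect_equal(alt$estimate$u_hat, base$estimate$u_hat, tolerance = 1e-9)
  }
})

test_that("the estimator is affine in the measurements", {
  fx <- small_fixture()
  agg <- fx$agg
  T <- fx$T_rec
  u_a <- artifact_inputs(agg$models[[length(agg$models)]]$template, 1, T)
  set.seed(7)
  y1 <- matrix(rnorm(36 * T), 36)
  y2 <- matrix(rnorm(36 * T), 36)
  est <- function(y) estimate_inputs(y, agg, u_a, lambda = 1e-2)$u_hat
  expect_equal(est(y1 + y2), est(y1) + est(y2) - est(matrix(0, 36, T)),
               tolerance = 1e-8)
})

test_that("duplicated neurons are flagged as unidentifiable", {
  fx <- small_fixture()
  twin <- fx$ei_models[[1]]
  twin$id <- 99L
  agg <- assemble(c(fx$ei_models, list(twin)))
  expect_error(build_window_operator(agg, L = 10), "identifiable")
})

test_that("input estimation validates its inputs", {
  fx <- small_fixture()
  y <- matrix(0, 36, fx$T_rec)
  expect_error(estimate_inputs(y[, 1:5], fx$agg, L = 10), "window length")
  y[1, 1] <- NA
  expect_error(estimate_inputs(y, fx$agg, L = 10), "finite")
})

test_that("input RMSE grows with output noise and with active neurons", {
  fx <- small_fixture()
  ns <- noise_sensitivity_study(fx, noise_stds = c(0, 1, 4), reps = 8)
  for (k in unique(ns$n_fire))
    expect_true(all(diff(ns$rmse[ns$n_fire == k]) >= 0))
  for (s in unique(ns$noise_std))
    expect_gte(ns$rmse[ns$n_fire == 3 & ns$noise_std == s],
               ns$rmse[ns$n_fire == 1 & ns$noise_std == s])
  r <- recovery_experiment(fx, 0L, lambda = 0)
  expect_equal(input_rmse(r$estimate, r$u_true)$rmse, rep(0, 4),
               tolerance = 1e-7)
})
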