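test_that("a single-model aggregate reproduces the standalone simulation", {
  fx <- small_fixture()
  mod <- fx$ei_models[[1]]
  agg <- assemble(list(mod))
  T <- 40
  u <- template_inputs(agg, stats::setNames(5L, mod$id), T)
  y_agg <- simulate_aggregate(agg, u)
  u_solo <- matrix(0, 2, T)
  times <- mod$template$pulse_times + 5L + 1L
  u_solo[cbind(1:2, times)] <- 1
  y_solo <- simulate_lds(mod, u_solo)
  expect_equal(y_agg, y_solo, tolerance = 1e-12)
})

test_that("aggregate state dimension and slices follow the block structure", {
  fx <- small_fixture()
  agg <- fx$agg
  sizes <- vapply(c(fx$ei_models, list(fx$artifact_model)),
                  function(m) length(m$electrode_subset), integer(1))
  expect_equal(nrow(agg$A), sum(sizes))
  expect_equal(ncol(agg$B), 2 * length(fx$ei_models))
  expect_equal(ncol(agg$Bp), 3)
  covered <- sort(unlist(lapply(agg$slices, `[[`, "states")))
  expect_equal(covered, seq_len(nrow(agg$A)))
})

test_that("outputs superpose across sub-models and decompositions", {
  fx <- small_fixture()
  agg <- fx$agg
  T <- fx$T_rec
  ids <- vapply(fx$ei_models, function(m) as.integer(m$id), integer(1))
  u1 <- template_inputs(agg, stats::setNames(8L, ids[1]), T)
  u2 <- template_inputs(agg, stats::setNames(11L, ids[2]), T)
  y12 <- simulate_aggregate(agg, u1 + u2)
  expect_equal(y12, simulate_aggregate(agg, u1) + simulate_aggregate(agg, u2),
               tolerance = 1e-10)
  # all-zero inputs give an all-zero output
  expect_true(all(simulate_aggregate(agg, matrix(0, ncol(agg$B), T)) == 0))
  # neurons with disjoint subsets contribute to disjoint electrodes
  subs <- lapply(fx$ei_models, function(m) m$electrode_subset)
  pairs <- utils::combn(length(subs), 2)
  disjoint <- which(vapply(seq_len(ncol(pairs)), function(j)
    length(intersect(subs[[pairs[1, j]]], subs[[pairs[2, j]]])) == 0,
    logical(1)))
  if (length(disjoint) > 0) {
    a <- pairs[1, disjoint[1]]; b <- pairs[2, disjoint[1]]
    u <- template_inputs(agg, stats::setNames(c(8L, 8L), ids[c(a, b)]), T)
    y <- simulate_aggregate(agg, u)
    ya <- simulate_aggregate(agg, template_inputs(agg, stats::setNames(8L, ids[a]), T))
    expect_equal(y[subs[[a]] + 1, ], ya[subs[[a]] + 1, ], tolerance = 1e-12)
  }
})

test_that("output noise is seeded and reproducible", {
  fx <- small_fixture()
  u <- template_inputs(fx$agg, stats::setNames(8L, 0L), fx$T_rec)
  y1 <- simulate_aggregate(fx$agg, u, noise = noise_model(2), seed = 42)
  y2 <- simulate_aggregate(fx$agg, u, noise = noise_model(2), seed = 42)
  expect_identical(y1, y2)
  y3 <- simulate_aggregate(fx$agg, u, noise = noise_model(2), seed = 43)
  expect_false(identical(y1, y3))
})

test_that("assembly rejects inconsistent sub-models", {
  fx <- small_fixture()
  other <- random_lds(1, E = 99)
  expect_error(assemble(list(fx$ei_models[[1]], other)), "disagree")
  expect_error(assemble(list()), "at least one")
  expect_error(simulate_aggregate(assemble(fx$ei_models),
                                  artifact_input = matrix(0, 3, 10)),
               "no artifact")
})
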