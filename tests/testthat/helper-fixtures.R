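# Shared fixtures, built lazily and cached per test file.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small standard preparation: 6x6 array, 4 neurons, artifact at the centre
small_fixture <- function() {
  cached("small", function()
    demo_models(seed = 1, rows = 6, cols = 6, n_neurons = 4,
                with_artifact = TRUE, artifact_radius = 100))
}

# a random stable state-space model embedded in E electrodes
random_lds <- function(seed, m = 4, E = 12, P = 2, role = "ei",
                       pulse_times = c(5L, 11L), T_u = 40) {
  set.seed(seed)
  A <- matrix(rnorm(m * m), m)
  A <- A * (0.8 / max(Mod(eigen(A, only.values = TRUE)$values)))
  B <- matrix(rnorm(m * P), m)
  pulses <- matrix(0, P, T_u)
  for (i in seq_len(P)) pulses[i, pulse_times[i] + 1] <- 1
  tmpl <- input_template(pulses, pulse_times, role)
  subset <- sort(sample(0:(E - 1), m))
  id <- if (role == "artifact") setdiff(0:(E - 1), subset)[1] else 0L
  state_space_model(A, B, subset, tmpl, role, id = id, n_electrodes = E)
}

# toy biphasic trace on a single-electrode-dominant EI
toy_biphasic_ei <- function(trace = c(0, -1, -2, -1, 0, 1, 2, 1, 0)) {
  v <- rbind(trace, 0.5 * trace)
  electrical_image(0L, v)
}
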