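#' Synthetic neuron specification
#'
#' Describes a neuron for the synthetic electrical-image generator: a soma
#' position, an axon path along which the spike propagates, and waveform
#' parameters. The generated EI is a biphasic (trough-then-overshoot)
#' waveform whose latency grows with arc-length along the axon and whose
#' amplitude decays exponentially with distance from the path.
#'
#' @param soma_position length-2 numeric, soma coordinates in micrometres.
#' @param axon_path k x 2 matrix of way-points (micrometres) starting at the
#'   soma; defaults to the soma alone (point source).
#' @param peak_amplitude global EI peak in microvolts (> 0).
#' @param spike_width approximate trough width in samples.
#' @param conduction_speed axonal conduction speed in micrometres per sample
#'   (50 um/sample at 20 kHz is 1 m/s).
#' @param decay_length spatial decay constant of the EI amplitude (um).
#' @return an object of class `synthetic_neuron_spec`.
#' @export
synthetic_neuron_spec <- function(soma_position, axon_path = NULL,
                                  peak_amplitude = 100, spike_width = 6,
                                  conduction_speed = 50, decay_length = 40) {
  if (peak_amplitude <= 0) stop("peak_amplitude must be > 0")
  if (conduction_speed <= 0) stop("conduction_speed must be > 0")
  if (decay_length <= 0) stop("decay_length must be > 0")
  if (is.null(axon_path)) axon_path <- matrix(soma_position, 1, 2)
  axon_path <- as.matrix(axon_path)
  stopifnot(ncol(axon_path) == 2)
  structure(list(soma_position = as.numeric(soma_position),
                 axon_path = axon_path,
                 peak_amplitude = peak_amplitude,
                 spike_width = spike_width,
                 conduction_speed = conduction_speed,
                 decay_length = decay_length),
            class = "synthetic_neuron_spec")
}

# Densify an axon path to ~2 um steps; returns points plus cumulative
# arc-length from the first way-point.
densify_path <- function(path, step = 2) {
  if (nrow(path) == 1)
    return(list(pts = path, arc = 0))
  pts <- path[1, , drop = FALSE]
  arc <- 0
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2, ceiling(len / step))
    s <- seq(0, 1, length.out = n)[-1]
    seg <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
    pts <- rbind(pts, seg)
    arc <- c(arc, arc[length(arc)] + s * len)
  }
  list(pts = pts, arc = arc)
}

# Biphasic extracellular spike waveform: dominant negative lobe followed by
# a smaller positive overshoot (difference of Gaussians), onset at t0.
biphasic_waveform <- function(t, t0, width) {
  s1 <- width / 2.355                 # FWHM -> sd of the trough
  s2 <- 1.6 * s1
  -exp(-(t - t0)^2 / (2 * s1^2)) + 0.45 * exp(-(t - t0 - width)^2 / (2 * s2^2))
}

#' Generate a synthetic electrical image
#'
#' Each electrode's trace is the biphasic spike waveform delayed by the
#' conduction time to the nearest axon-path point and attenuated by
#' `exp(-d / decay_length)` where `d` is the distance from the electrode to
#' the path; the whole EI is scaled so its global extremum magnitude equals
#' `spec$peak_amplitude`. The construction is deterministic; `seed` is
#' accepted for bookkeeping symmetry with the stochastic generators.
#'
#' @param array an [electrode_array].
#' @param spec a [synthetic_neuron_spec].
#' @param T number of time samples.
#' @param neuron_id id stored on the EI.
#' @param t_onset lead-in before the somatic trough, in samples.
#' @param seed unused (the generator is deterministic).
#' @return an [electrical_image].
#' @export
gen_synthetic_ei <- function(array, spec, T = 71, neuron_id = 0L,
                             t_onset = 10, seed = NULL) {
  dp <- densify_path(spec$axon_path)
  # per-electrode distance to the path and arc-length of the closest point
  E <- n_electrodes(array)
  d <- numeric(E); s <- numeric(E)
  for (e in seq_len(E)) {
    dd <- (dp$pts[, 1] - array$x[e])^2 + (dp$pts[, 2] - array$y[e])^2
    i <- which.min(dd)
    d[e] <- sqrt(dd[i]); s[e] <- dp$arc[i]
  }
  lat <- t_onset + s / spec$conduction_speed
  span <- max(lat) + 2 * spec$spike_width
  if (T < span)
    stop(sprintf("T = %d too small for the propagation span (%.0f samples)",
                 T, ceiling(span)))
  amp <- exp(-d / spec$decay_length)
  tt <- seq_len(T) - 1
  v <- t(vapply(seq_len(E),
                function(e) amp[e] * biphasic_waveform(tt, lat[e], spec$spike_width),
                numeric(T)))
  v <- v * (spec$peak_amplitude / max(abs(v)))
  electrical_image(neuron_id, v)
}

#' Generate the unit-amplitude stimulation-artifact ground truth
#'
#' The artifact transient is the sum of a fast and a slow exponential decay
#' (defaults ~5 and ~40 samples; 40 samples at 20 kHz is the ~2 ms tail),
#' each propagating radially outward from the stimulating electrode with its
#' own spatial decay length: the slow (Faradaic-like) component spreads
#' `slow_spread` times farther than the fast (capacitive-like) one. The
#' first post-stimulus sample (t = 0) is baseline zero. The trace recorded
#' at stimulus amplitude `q` is `q` times this matrix.
#'
#' @param array an [electrode_array].
#' @param stim_electrode stimulating electrode id.
#' @param T number of time samples.
#' @param decay_length spatial decay constant of the fast component (um).
#' @param time_constant slow temporal decay constant in samples.
#' @param tau_fast fast temporal decay constant in samples.
#' @param slow_weight relative amplitude of the slow component.
#' @param slow_spread spatial spread of the slow component relative to
#'   `decay_length`.
#' @param peak_per_uA global peak magnitude per unit amplitude (uV/uA).
#' @return an `E x T` matrix: the artifact per unit stimulation amplitude.
#' @export
gen_artifact_truth <- function(array, stim_electrode, T = 55,
                               decay_length = 100, time_constant = 40,
                               tau_fast = 5, slow_weight = 0.4,
                               slow_spread = 1.5, peak_per_uA = 60) {
  if (time_constant <= 0 || tau_fast <= 0) stop("time constants must be > 0")
  p <- electrode_xy(array, stim_electrode)
  d <- sqrt((array$x - p[1])^2 + (array$y - p[2])^2)
  g_fast <- exp(-d / decay_length)
  g_slow <- slow_weight * exp(-d / (slow_spread * decay_length))
  af <- exp(-1 / tau_fast); as <- exp(-1 / time_constant)
  tt <- seq_len(T) - 1                      # 0-based time
  k_fast <- ifelse(tt == 0, 0, af^(tt - 1))
  k_slow <- ifelse(tt == 0, 0, as^(tt - 1))
  M <- outer(g_fast, k_fast) + outer(g_slow, k_slow)
  M * (peak_per_uA / max(abs(M)))
}

#' Log-spaced amplitude grid
#'
#' @param n number of amplitudes (>= 2).
#' @param lo,hi endpoints in microamperes, `0 < lo < hi`.
#' @return strictly increasing vector of `n` log-spaced currents with the
#'   exact endpoints.
#' @export
gen_amplitude_grid <- function(n = 39, lo = 0.1, hi = 4.1) {
  if (lo <= 0) stop("lo must be > 0")
  if (hi <= lo) stop("hi must exceed lo")
  if (n < 2) stop("n must be >= 2")
  q <- exp(seq(log(lo), log(hi), length.out = n))
  q[1] <- lo; q[n] <- hi
  q
}

#' Triphasic stimulation current waveform
#'
#' Three equal-duration phases with currents in the protocol's relative
#' ratios (default 2:-3:1), scaled so the second-phase magnitude equals
#' `amplitude`. The net charge (sum of current x duration) is zero.
#'
#' @param amplitude second-phase current magnitude in microamperes (>= 0).
#' @param protocol a [stim_protocol].
#' @param sampling_rate sampling rate in Hz.
#' @return numeric vector of instantaneous current, one value per sample.
#' @export
gen_stim_waveform <- function(amplitude, protocol = stim_protocol(),
                              sampling_rate = 20000) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  spp <- max(1L, as.integer(round(protocol$phase_duration_us * 1e-6 * sampling_rate)))
  currents <- protocol$phase_ratios / abs(protocol$phase_ratios[2]) * amplitude
  rep(currents, each = spp)
}

#' Ground-truth container for synthetic stimulation datasets
#'
#' @param activation data frame `neuron_id, q50_uA, slope`: per-neuron
#'   logistic activation parameters (probability of firing is logistic in
#'   log-amplitude with 50% point `q50_uA`).
#' @param spikes data frame `trial, neuron_id, latency_samples` of realised
#'   evoked spikes (filled in by [gen_stim_dataset()]).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(activation, spikes = NULL) {
  stopifnot(all(c("neuron_id", "q50_uA", "slope") %in% names(activation)))
  structure(list(activation = activation, spikes = spikes),
            class = "ground_truth")
}

#' Logistic activation probability
#'
#' Probability that a neuron fires at stimulation amplitude `q`:
#' `plogis((log(q) - log(q50)) / slope)`. An infinite `q50` encodes a neuron
#' that never activates.
#'
#' @param q amplitude(s) in microamperes.
#' @param q50 50% threshold in microamperes.
#' @param slope logistic scale on the log-amplitude axis.
#' @return activation probabilities in `[0, 1]`.
#' @export
activation_probability <- function(q, q50, slope) {
  if (is.infinite(q50)) return(rep(0, length(q)))
  stats::plogis((log(q) - log(q50)) / slope)
}

#' Generate a trial-structured synthetic stimulation dataset
#'
#' For every amplitude x repeat of the protocol, each neuron fires a spike
#' with the logistic probability given by the ground truth; a firing
#' neuron's EI is inserted at a latency drawn uniformly from
#' `latency_range` (samples). The trial trace is the superposition
#' `q * artifact + sum of shifted EIs + Gaussian noise`.
#'
#' @param array an [electrode_array].
#' @param eis list of [electrical_image] objects on that array.
#' @param artifact_truth `E x T` unit-amplitude artifact matrix (or `NULL`
#'   for artifact-free data).
#' @param protocol a [stim_protocol].
#' @param truth a [ground_truth] with activation parameters for every EI.
#' @param noise a [noise_model].
#' @param latency_range integer range (lo, hi) of evoked-spike latencies in
#'   samples; the default 8-12 samples is 0.4-0.6 ms at 20 kHz.
#' @param stim_electrode stimulating electrode id stored on the recording.
#' @param T post-stimulus window length in samples.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return list with elements `recording` (a [recording]) and `truth` (the
#'   input [ground_truth] with realised `spikes` filled in).
#' @export
gen_stim_dataset <- function(array, eis, artifact_truth, protocol, truth,
                             noise = noise_model(1), latency_range = c(8, 12),
                             stim_electrode, T = 55, seed = 1) {
  E <- n_electrodes(array)
  lats <- seq.int(latency_range[1], latency_range[2])
  if (any(lats < 0) || any(lats >= T))
    stop("latency_range must lie inside the post-stimulus window")
  if (!is.null(artifact_truth))
    stopifnot(nrow(artifact_truth) == E, ncol(artifact_truth) == T)
  act <- truth$activation
  ids <- vapply(eis, function(e) as.integer(e$neuron_id), integer(1))
  stopifnot(all(ids %in% act$neuron_id))
  q50 <- act$q50_uA[match(ids, act$neuron_id)]
  slope <- act$slope[match(ids, act$neuron_id)]

  amps <- rep(protocol$amplitudes, each = protocol$repeats)
  n_trials <- length(amps)
  data <- base::array(0, dim = c(n_trials, T, E))
  spikes <- vector("list", n_trials)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (tr in seq_len(n_trials)) {
    q <- amps[tr]
    trial <- if (is.null(artifact_truth)) matrix(0, E, T) else q * artifact_truth
    fired <- stats::runif(length(eis)) <
      vapply(seq_along(eis), function(i) activation_probability(q, q50[i], slope[i]),
             numeric(1))
    lat <- integer(0)
    if (any(fired)) {
      lat <- sample(lats, sum(fired), replace = TRUE)
      k <- 0
      for (i in which(fired)) {
        k <- k + 1
        v <- eis[[i]]$voltages
        n_cols <- min(ncol(v), T - lat[k])
        cols <- lat[k] + seq_len(n_cols)        # 1-based columns lat+1 ..
        trial[, cols] <- trial[, cols] + v[, seq_len(n_cols)]
      }
    }
    if (noise$std > 0)
      trial <- trial + matrix(stats::rnorm(E * T, sd = noise$std), E, T)
    data[tr, , ] <- t(trial)
    if (any(fired))
      spikes[[tr]] <- data.frame(trial = tr, neuron_id = ids[fired],
                                 latency_samples = lat)
  }
  spikes <- if (all(vapply(spikes, is.null, logical(1)))) {
    data.frame(trial = integer(0), neuron_id = integer(0),
               latency_samples = integer(0))
  } else do.call(rbind, spikes)
  rownames(spikes) <- NULL
  list(recording = recording(data, amps, stim_electrode),
       truth = ground_truth(act, spikes))
}
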