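#' Electrical image of a neuron
#'
#' The electrical image (EI) is the mean spatiotemporal voltage footprint of
#' one neuron's spike across the whole array: an `E x T` matrix in microvolts
#' at a given sampling rate. The peak amplitude (max absolute voltage over all
#' electrodes and samples) is derived on construction.
#'
#' @param neuron_id identifier (integer or character).
#' @param voltages numeric matrix, electrodes x time samples, in microvolts.
#' @param sampling_rate sampling rate in Hz (default 20 kHz).
#' @return an object of class `electrical_image`.
#' @export
electrical_image <- function(neuron_id, voltages, sampling_rate = 20000) {
  voltages <- as.matrix(voltages)
  if (ncol(voltages) < 2) stop("an EI needs at least 2 time samples")
  if (!all(is.finite(voltages))) stop("EI voltages must be finite")
  structure(
    list(neuron_id = neuron_id, voltages = voltages,
         sampling_rate = sampling_rate,
         peak_amplitude = max(abs(voltages))),
    class = "electrical_image")
}

#' @export
print.electrical_image <- function(x, ...) {
  cat(sprintf("<electrical_image> neuron %s: %d electrodes x %d samples, peak %.1f uV\n",
              format(x$neuron_id), nrow(x$voltages), ncol(x$voltages),
              x$peak_amplitude))
  invisible(x)
}

#' Input template of a state-space model
#'
#' A short multi-channel pulse sequence that drives a state-space model to
#' reproduce its target signal. EI templates carry two unit-magnitude pulses
#' (trigger of the depolarisation and repolarisation phases); artifact
#' templates carry three pulses at the stimulation onset, scaled by the
#' stimulus current at use.
#'
#' @param pulses numeric matrix, channels x time.
#' @param pulse_times 0-based sample indices of the pulses (one per channel).
#' @param role `"ei"` or `"artifact"`.
#' @return an object of class `input_template`.
#' @export
input_template <- function(pulses, pulse_times, role = c("ei", "artifact")) {
  role <- match.arg(role)
  pulses <- as.matrix(pulses)
  p_expected <- if (role == "ei") 2L else 3L
  if (nrow(pulses) != p_expected)
    stop(sprintf("%s templates have %d pulse channels", role, p_expected))
  if (role == "ei" && !all(abs(pulses[pulses != 0]) == 1))
    stop("EI template pulses must have unit magnitude")
  structure(list(pulses = pulses, pulse_times = as.integer(pulse_times),
                 role = role),
            class = "input_template")
}

#' @export
print.input_template <- function(x, ...) {
  cat(sprintf("<input_template> role %s: %d channels x %d samples, pulses at t = %s\n",
              x$role, nrow(x$pulses), ncol(x$pulses),
              paste(x$pulse_times, collapse = ", ")))
  invisible(x)
}

#' Trial-structured post-stimulation recording
#'
#' Voltage traces recorded on all electrodes for every stimulation trial.
#' Time sample `t = 0` (column 1) is the first sample after stimulus offset.
#'
#' @param data numeric array, trials x time x electrodes, microvolts.
#' @param amplitudes per-trial stimulation current on the second phase, in
#'   microamperes (>= 0).
#' @param stim_electrode id of the stimulating electrode.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `recording`.
#' @export
recording <- function(data, amplitudes, stim_electrode, sampling_rate = 20000) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(amplitudes))
  if (!all(is.finite(data))) stop("recording data must be finite")
  if (any(amplitudes < 0)) stop("stimulation amplitudes must be >= 0")
  structure(
    list(data = data, amplitudes = as.numeric(amplitudes),
         stim_electrode = as.integer(stim_electrode),
         sampling_rate = sampling_rate),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d trials x %d samples x %d electrodes, stim electrode %d, %d amplitudes\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$stim_electrode,
    length(unique(x$amplitudes))))
  invisible(x)
}

#' Subset a recording by trial index
#'
#' @param rec a [recording].
#' @param trials 1-based trial indices to keep.
#' @return a [recording] with the selected trials.
#' @export
subset_trials <- function(rec, trials) {
  recording(rec$data[trials, , , drop = FALSE], rec$amplitudes[trials],
            rec$stim_electrode, rec$sampling_rate)
}

#' Stimulation protocol
#'
#' The defaults reproduce the standard epiretinal stimulation protocol:
#' 39 log-spaced current amplitudes from 0.1 to 4.1 uA on the second phase,
#' each repeated 25 times, delivered as a charge-balanced triphasic pulse
#' (50 us per phase, relative phase ratios 2:-3:1).
#'
#' @param amplitudes strictly increasing currents in microamperes.
#' @param repeats trials per amplitude (>= 1).
#' @param phase_ratios relative currents of the three phases; must sum to
#'   zero (charge balance).
#' @param phase_duration_us duration of each phase in microseconds.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(amplitudes = gen_amplitude_grid(39, 0.1, 4.1),
                          repeats = 25,
                          phase_ratios = c(2, -3, 1),
                          phase_duration_us = 50) {
  if (any(diff(amplitudes) <= 0)) stop("amplitudes must be strictly increasing")
  if (repeats < 1) stop("repeats must be >= 1")
  if (abs(sum(phase_ratios)) > 1e-12)
    stop("phase_ratios must sum to zero (charge balance)")
  structure(list(amplitudes = as.numeric(amplitudes),
                 repeats = as.integer(repeats),
                 phase_ratios = as.numeric(phase_ratios),
                 phase_duration_us = phase_duration_us),
            class = "stim_protocol")
}

#' Additive measurement-noise model
#'
#' @param std standard deviation in microvolts (>= 0).
#' @param kind only `"gaussian"` (i.i.d.) is supported.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(std = 1, kind = "gaussian") {
  if (std < 0) stop("noise std must be >= 0")
  kind <- match.arg(kind, "gaussian")
  structure(list(std = std, kind = kind), class = "noise_model")
}
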