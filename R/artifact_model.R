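#' Trial-averaged trace at one amplitude
#'
#' Per-electrode, per-sample trimmed mean over the trials recorded at the
#' given amplitude. Trimming (fraction discarded from each tail, R's
#' `mean(trim = )` convention) resists contamination by evoked spikes,
#' which appear only on a subset of trials.
#'
#' @param rec a [recording].
#' @param amplitude stimulation amplitude to average (matched exactly, up to
#'   floating-point tolerance).
#' @param trim trim fraction in `[0, 0.5)`.
#' @return an `E x T` matrix in microvolts.
#' @export
average_trials <- function(rec, amplitude, trim = 0.1) {
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  idx <- which(abs(rec$amplitudes - amplitude) <= 1e-9 * max(1, abs(amplitude)))
  if (length(idx) == 0) stop("no trials at amplitude ", amplitude)
  dat <- rec$data[idx, , , drop = FALSE]          # trials x T x E
  if (length(idx) == 1) return(t(dat[1, , ]))
  avg <- if (trim == 0) {
    colMeans(dat)                                  # T x E
  } else {
    apply(dat, c(2, 3), mean, trim = trim)
  }
  t(avg)
}

#' Select the state electrodes of the artifact model
#'
#' The artifact decays radially, so only electrodes within `radius` of the
#' stimulating electrode are modelled. The stimulating electrode itself is
#' structurally excluded (its artifact is largest and behaves nonlinearly
#' with amplitude).
#'
#' @param array an [electrode_array].
#' @param stim_electrode stimulating electrode id.
#' @param radius selection radius in micrometres (> 0).
#' @return electrode ids (ascending), never containing `stim_electrode`.
#' @export
select_artifact_electrodes <- function(array, stim_electrode, radius = 150) {
  if (radius <= 0) stop("radius must be > 0")
  sel <- neighbors_within(array, stim_electrode, radius, include_center = FALSE)
  if (length(sel) == 0)
    stop("no electrodes within ", radius, " um of the stimulating electrode")
  sel
}

#' Three-pulse artifact input template
#'
#' The template has three unit-scale pulses on separate channels at the
#' first three post-stimulus samples (t = 0, 1, 2); the per-channel gains
#' are absorbed into `B` during [fit_artifact_model()]. The template is
#' amplitude-independent and is scaled by the stimulus current `q` at use
#' (`u_a^t = q r_a^t`).
#'
#' @param averaged list of per-amplitude trial-averaged `E x T` matrices
#'   (at least two amplitudes; only the time base is taken from them).
#' @param subset state electrode ids (unused by the construction; kept for
#'   interface symmetry with the fit).
#' @return an [input_template] with `role = "artifact"`.
#' @export
fit_artifact_template <- function(averaged, subset = NULL) {
  if (length(averaged) < 2) stop("need averaged data at >= 2 amplitudes")
  T <- ncol(averaged[[1]])
  if (T < 4) stop("fewer than 3 usable onset samples in the averaged data")
  pulses <- matrix(0, 3, T)
  pulses[cbind(1:3, 1:3)] <- 1
  input_template(pulses, pulse_times = 0:2, role = "artifact")
}

#' Fit the stimulation-artifact state-space model
#'
#' States are the trial-averaged voltages on the subset electrodes. The
#' artifact is linear in the stimulus current, so the fitting amplitudes
#' are pooled into one least-squares estimate of the *unit-amplitude*
#' artifact trajectory, which is then realised as a stable low-order modal
#' system driven by the three onset pulses (`u_a = q r_a`): eigenvalues
#' from the free decay after the onset, spatial mode profiles by least
#' squares, onset `B` columns absorbing the first samples exactly. Supply
#' only low-contamination amplitudes — ideally below the lowest activation
#' threshold — because evoked spikes in the trial averages are absorbed
#' into the model and extrapolate with `q`. The per-amplitude ANRMSE on
#' the supplied data is stored in `$fit$anrmse`.
#'
#' @param averaged list of `E x T` trial-averaged matrices, one per fitting
#'   amplitude.
#' @param amplitudes the corresponding currents in microamperes.
#' @param subset state electrode ids (must exclude the stimulating
#'   electrode), e.g. from [select_artifact_electrodes()].
#' @param stim_electrode stimulating electrode id.
#' @param template an [input_template]; defaults to
#'   [fit_artifact_template()]. Pulses must sit at the first three samples.
#' @param ridge damping of the least-squares mode refits (0 is exact on
#'   identifiable data).
#' @param max_order maximum number of retained modes.
#' @param stability_cap eigenvalue magnitude clamp.
#' @param stability_tol spectral-radius warning tolerance.
#' @return a [state_space_model] with role `"artifact"`.
#' @export
fit_artifact_model <- function(averaged, amplitudes, subset, stim_electrode,
                               template = NULL, ridge = 0, max_order = 12,
                               stability_cap = 0.995, stability_tol = 0.05) {
  stopifnot(length(averaged) == length(amplitudes))
  if (stim_electrode %in% subset)
    stop("the stimulating electrode must not be in the artifact state subset")
  if (is.null(template)) template <- fit_artifact_template(averaged)
  if (!identical(template$pulse_times, 0:2) &&
      !identical(template$pulse_times, as.integer(0:2)))
    stop("artifact template pulses must sit at samples 0, 1, 2")
  E <- nrow(averaged[[1]])
  # pooled least-squares estimate of the unit-amplitude trajectory
  Xbar <- Reduce(`+`, Map(function(X, q) q * X[subset + 1L, , drop = FALSE],
                          averaged, amplitudes)) / sum(amplitudes^2)
  if (max(abs(Xbar)) == 0)
    stop("rank-deficient fit: averaged artifact is zero on the subset")
  fit <- modal_realization_onset(Xbar, n_pulses = 3, max_order = max_order,
                                 stability_cap = stability_cap, ridge = ridge)
  gains <- template$pulses[cbind(1:3, 1:3)]
  if (any(gains == 0)) stop("artifact template onset pulses must be nonzero")
  B <- sweep(fit$B, 2, gains, "/")
  model <- state_space_model(
    A = fit$A, B = B,
    electrode_subset = subset, template = template, role = "artifact",
    id = stim_electrode, n_electrodes = E, stability_tol = stability_tol)
  err <- vapply(seq_along(averaged), function(j) {
    pred <- simulate_lds(model, amplitudes[j] * template$pulses)
    anrmse(averaged[[j]], pred, subset)
  }, numeric(1))
  model$fit <- list(anrmse = data.frame(amplitude_uA = amplitudes, anrmse = err),
                    ridge = ridge, order = fit$order)
  model
}

#' Artifact-normalised root-mean-square error
#'
#' `RMS(measured - predicted) / RMS(measured)` over the subset electrodes
#' and all samples. The stimulating electrode is never part of the subset,
#' so its trace never enters the metric.
#'
#' @param measured,predicted `E x T` matrices.
#' @param subset electrode ids over which the error is measured.
#' @return a nonnegative scalar.
#' @export
anrmse <- function(measured, predicted, subset) {
  measured <- as.matrix(measured); predicted <- as.matrix(predicted)
  if (!all(dim(measured) == dim(predicted))) stop("shape mismatch")
  rows <- subset + 1L
  den <- sqrt(mean(measured[rows, ]^2))
  if (den == 0) stop("measured artifact has zero RMS over the subset")
  sqrt(mean((measured[rows, ] - predicted[rows, ])^2)) / den
}

#' Default low-contamination fitting amplitudes
#'
#' The artifact model is identified on the lower part of the amplitude grid,
#' where few or no spikes are evoked and the trial average is artifact-only.
#'
#' @param amplitudes full amplitude grid (ascending).
#' @param frac fraction of the grid to keep from the low end.
#' @return the selected amplitudes.
#' @export
fitting_amplitudes <- function(amplitudes, frac = 0.5) {
  amplitudes[seq_len(max(2, ceiling(length(amplitudes) * frac)))]
}
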