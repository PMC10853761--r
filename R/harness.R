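#' Standard synthetic fixture: array, neurons, fitted models
#'
#' Builds the package's reference synthetic preparation: a grid MEA, a set
#' of synthetic neurons with axons crossing the array, their EIs, fitted EI
#' models, the unit-amplitude artifact ground truth for a stimulating
#' electrode, an artifact model fitted from noiseless per-amplitude
#' averages, and the assembled aggregate model. All placement is a
#' deterministic function of `seed`.
#'
#' @param seed integer seed controlling neuron placement.
#' @param rows,cols,pitch array geometry.
#' @param n_neurons number of synthetic neurons.
#' @param stim_electrode stimulating electrode id (default: array centre).
#' @param T_ei,T_rec EI and post-stimulus window lengths in samples.
#' @param ridge_ei,ridge_artifact identification ridge penalties.
#' @param artifact_radius state-electrode radius of the artifact model (um).
#' @param with_artifact include the artifact model in the aggregate?
#' @return list with `array`, `specs`, `eis`, `ei_models`,
#'   `artifact_truth`, `artifact_model`, `agg`, `stim_electrode`,
#'   `T_rec`.
#' @export
demo_models <- function(seed = 1, rows = 16, cols = 16, pitch = 60,
                        n_neurons = 8, stim_electrode = NULL,
                        T_ei = 71, T_rec = 55, ridge_ei = 0,
                        ridge_artifact = 0, artifact_radius = 150,
                        with_artifact = TRUE) {
  arr <- build_grid_geometry(rows, cols, pitch)
  if (is.null(stim_electrode))
    stim_electrode <- arr$ids[floor(rows / 2) * cols + floor(cols / 2)]
  w <- (cols - 1) * pitch; h <- (rows - 1) * pitch

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  specs <- lapply(seq_len(n_neurons), function(i) {
    soma <- c(stats::runif(1, 0.15 * w, 0.85 * w),
              stats::runif(1, 0.15 * h, 0.85 * h))
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 250, 400)
    path <- rbind(soma, soma + len * c(cos(ang), sin(ang)))
    synthetic_neuron_spec(soma, path,
                          peak_amplitude = stats::runif(1, 60, 120))
  })
  eis <- lapply(seq_len(n_neurons), function(i)
    gen_synthetic_ei(arr, specs[[i]], T = T_ei, neuron_id = i - 1L))
  ei_models <- lapply(eis, fit_ei_model, ridge = ridge_ei)

  artifact_truth <- gen_artifact_truth(arr, stim_electrode, T = T_rec)
  artifact_model <- NULL
  if (with_artifact) {
    fit_amps <- fitting_amplitudes(gen_amplitude_grid(39, 0.1, 4.1))
    averaged <- lapply(fit_amps, function(q) q * artifact_truth)
    subset <- select_artifact_electrodes(arr, stim_electrode, artifact_radius)
    artifact_model <- fit_artifact_model(averaged, fit_amps, subset,
                                         stim_electrode,
                                         ridge = ridge_artifact)
  }
  list(array = arr, specs = specs, eis = eis, ei_models = ei_models,
       artifact_truth = artifact_truth, artifact_model = artifact_model,
       agg = assemble(ei_models, artifact_model),
       stim_electrode = stim_electrode, T_rec = T_rec)
}

#' Noiseless template round trip through the aggregate model
#'
#' Generates a trial by injecting the templates of the given neurons (at a
#' common latency) plus the artifact input into the aggregate model, then
#' inverts it with the input estimator and calls spikes. In the noiseless
#' case the estimator reproduces the injected templates exactly.
#'
#' @param fx a [demo_models()] fixture.
#' @param firing_ids neuron ids to fire.
#' @param latency spike latency in samples.
#' @param q stimulus amplitude driving the artifact (uA).
#' @param noise_std output-noise standard deviation (uV).
#' @param excluded corrupted electrode ids (`"stim"` for the stimulating
#'   electrode, `integer(0)` for none).
#' @param lambda estimator ridge; 0 gives the exact inverse.
#' @param L estimator window.
#' @param seed noise seed.
#' @return list with `estimate`, `rmse` (per-neuron, vs the injected
#'   inputs), `calls` (from [detect()]) and `u_true`.
#' @export
recovery_experiment <- function(fx, firing_ids, latency = 10, q = 1,
                                noise_std = 0, excluded = integer(0),
                                lambda = 0, L = 10, seed = 1) {
  agg <- fx$agg
  if (identical(excluded, "stim")) excluded <- fx$stim_electrode
  T <- fx$T_rec
  u_true <- template_inputs(
    agg, stats::setNames(rep(latency, length(firing_ids)), firing_ids), T)
  u_a <- if (agg$has_artifact)
    artifact_inputs(agg$models[[length(agg$models)]]$template, q, T) else NULL
  y <- simulate_aggregate(agg, u_true, u_a,
                          noise = if (noise_std > 0) noise_model(noise_std),
                          seed = seed)
  est <- estimate_inputs(y, agg, u_a, excluded = excluded, L = L,
                         lambda = lambda)
  list(estimate = est, rmse = input_rmse(est, u_true),
       calls = detect(est, agg), u_true = u_true)
}

#' Input-estimation error as a function of measurement noise
#'
#' Repeats the template round trip at several output-noise levels for one
#' and several simultaneously firing neurons and reports the root mean
#' squared input error per condition. The firing sets are the spatially
#' most-overlapping neuron groups of the fixture (overlap is what couples
#' the estimates, mirroring evoked activity near one stimulation site),
#' and the Monte Carlo design uses common random numbers across conditions
#' with antithetic noise pairs: the estimator is linear, so this cancels
#' the noise-bias cross term exactly and the reported means estimate the
#' population values without it. With the default ridge, the shrinkage
#' bias grows with the number of active input blocks, so multi-neuron
#' firing is recovered (slightly) worse at every noise level.
#'
#' @param fx a [demo_models()] fixture.
#' @param noise_stds noise standard deviations in microvolts.
#' @param n_fire numbers of simultaneously firing neurons to test.
#' @param reps antithetic noise pairs per condition (2 draws each).
#' @param lambda estimator ridge.
#' @param seed noise seed.
#' @return data frame `noise_std, n_fire, rmse`.
#' @export
noise_sensitivity_study <- function(fx, noise_stds = c(0, 1, 2, 4),
                                    n_fire = c(1, 3), reps = 20,
                                    lambda = 1e-2, seed = 1) {
  agg <- fx$agg
  T <- fx$T_rec
  E <- agg$n_electrodes
  ids <- neuron_ids(agg)
  op <- build_window_operator(agg, 10, integer(0))
  solver <- window_solver(op, lambda)
  # greedy most-overlapping groups: seed with the pair sharing the most
  # electrodes, then grow by maximal added overlap
  subs <- lapply(agg$models[seq_len(agg$n_neurons)],
                 function(m) m$electrode_subset)
  N <- length(subs)
  ov <- vapply(subs, function(a)
    vapply(subs, function(b) length(intersect(a, b)), numeric(1)),
    numeric(N))
  diag(ov) <- 0
  pick <- arrayInd(which.max(ov), dim(ov))[1, ]
  order_grp <- c(pick[1], pick[2])
  while (length(order_grp) < N) {
    rest <- setdiff(seq_len(N), order_grp)
    gain <- vapply(rest, function(i) sum(ov[i, order_grp]), numeric(1))
    order_grp <- c(order_grp, rest[which.max(gain)])
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  E_unit <- base::array(stats::rnorm(E * T * reps), c(E, T, reps))
  E_unit <- base::array(c(E_unit, -E_unit), c(E, T, 2L * reps))
  out <- list()
  for (k in n_fire) {
    fire_idx <- order_grp[seq_len(k)]
    fire <- stats::setNames(rep(10L, k), ids[fire_idx])
    u_true <- template_inputs(agg, fire, T)
    y0 <- simulate_aggregate(agg, u_true)
    for (std in noise_stds) {
      y_arr <- base::array(rep(y0, 2L * reps), dim(E_unit)) + std * E_unit
      res <- estimate_inputs_batch(y_arr, agg, NULL, L = 10,
                                   lambda = lambda, op = op, solver = solver)
      msq <- mean(vapply(seq_len(2L * reps), function(j)
        mean((res$u_hat[, , j] - u_true)^2), numeric(1)))
      out[[length(out) + 1]] <- data.frame(noise_std = std, n_fire = k,
                                           rmse = sqrt(msq))
    }
  }
  do.call(rbind, out)
}

#' Agreement between the detector and the exhaustive oracle
#'
#' Generates noisy trials on a small fixture (random firing subsets and
#' latencies), sorts them with the input estimator plus similarity
#' detector, and independently with the brute-force enumeration oracle,
#' and reports the fraction of trials where the two return the same neuron
#' set.
#'
#' @param seed dataset seed.
#' @param n_trials number of trials.
#' @param noise_std output-noise standard deviation (uV).
#' @param rows,cols,n_neurons fixture size (defaults: 36 electrodes, 4
#'   neurons).
#' @param p_fire marginal firing probability per neuron and trial.
#' @param latency_range generator (and oracle) latency range.
#' @param lambda,threshold detector parameters.
#' @return list with `agreement` (fraction of trials), `n_trials`, and the
#'   per-trial comparison table.
#' @export
oracle_agreement_study <- function(seed = 1, n_trials = 200, noise_std = 1,
                                   rows = 6, cols = 6, n_neurons = 4,
                                   p_fire = 0.35, latency_range = 8:12,
                                   lambda = 1e-2, threshold = 0.5) {
  fx <- demo_models(seed, rows = rows, cols = cols, n_neurons = n_neurons,
                    with_artifact = TRUE, artifact_radius = 100)
  agg <- fx$agg
  T <- fx$T_rec
  ids <- neuron_ids(agg)
  q <- 1
  u_a <- artifact_inputs(agg$models[[length(agg$models)]]$template, q, T)
  y_art <- simulate_aggregate(agg, NULL, u_a)
  op <- build_window_operator(agg, 10, fx$stim_electrode)
  solver <- window_solver(op, lambda)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 1L)
  rows_out <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    fired <- ids[stats::runif(length(ids)) < p_fire]
    lats <- stats::setNames(sample(latency_range, length(fired), TRUE), fired)
    u_true <- template_inputs(agg, lats, T)
    y <- simulate_aggregate(agg, u_true, u_a)
    if (noise_std > 0)
      y <- y + matrix(stats::rnorm(length(y), sd = noise_std), nrow(y))
    est <- estimate_inputs(y, agg, u_a, excluded = fx$stim_electrode,
                           lambda = lambda, op = op)
    calls <- detect(est, agg, threshold = threshold)
    det_set <- sort(calls$neuron_id[calls$detected])
    orc <- oracle_enumerate(y, agg, u_a, excluded = fx$stim_electrode,
                            latency_range = latency_range,
                            noise_std = noise_std)
    rows_out[[tr]] <- data.frame(
      trial = tr,
      n_true = length(fired),
      agree = setequal(det_set, orc$neuron_ids),
      detector_correct = setequal(det_set, fired),
      oracle_correct = setequal(orc$neuron_ids, fired))
  }
  tab <- do.call(rbind, rows_out)
  list(agreement = mean(tab$agree), n_trials = n_trials, table = tab)
}

#' End-to-end threshold-recovery study
#'
#' The synthetic analogue of validating stimulation thresholds against a
#' reference: neurons with known logistic activation are stimulated over
#' the full protocol from several electrodes, the complete pipeline (EI
#' fits, artifact fit from trial averages, estimation, detection,
#' activation curves, sigmoid fits) is run, and recovered 50% thresholds
#' are compared with the generating truth. Optionally runs the K-fold
#' artifact validation on the first dataset.
#'
#' @param seed base seed.
#' @param n_stim number of stimulating electrodes (datasets); together with
#'   `n_neurons` this sets the number of neuron-electrode pairs.
#' @param rows,cols,n_neurons fixture size.
#' @param q50_range range (uA) spanned log-uniformly by the true 50%
#'   thresholds.
#' @param slope true logistic slope (log-amplitude scale).
#' @param noise_std measurement noise (uV).
#' @param protocol a [stim_protocol].
#' @param kfold_K folds for the K-fold validation (0 to skip).
#' @param lambda,threshold,L,latency_range,radius,trim,fit_frac,ridge
#'   pipeline parameters (see [sort_recording()], [kfold_activation()]).
#' @return list with `pairs` (data frame `stim_electrode, neuron_id,
#'   q50_true, q50_est, converged`), `r2` (Pearson R^2 true vs recovered),
#'   `median_rel_err` (median |q50_est - q50_true| / q50_true),
#'   `kfold_spread` (per-neuron (max-min)/truth over folds, first dataset)
#'   and the per-dataset call tables.
#' @export
threshold_recovery_study <- function(seed = 1, n_stim = 2, rows = 12,
                                     cols = 12, n_neurons = 5,
                                     q50_range = c(0.3, 2.5), slope = 0.1,
                                     noise_std = 1,
                                     protocol = stim_protocol(),
                                     kfold_K = 5, lambda = 1e-2,
                                     threshold = 0.5, L = 10,
                                     latency_range = 0:30, radius = Inf,
                                     trim = 0.25, fit_frac = 0.25,
                                     ridge = 0) {
  fx <- demo_models(seed, rows = rows, cols = cols, n_neurons = n_neurons,
                    with_artifact = FALSE)
  arr <- fx$array
  ids <- vapply(fx$eis, function(e) as.integer(e$neuron_id), integer(1))
  q50_true <- exp(seq(log(q50_range[1]), log(q50_range[2]),
                      length.out = n_neurons))
  truth <- ground_truth(data.frame(neuron_id = ids, q50_uA = q50_true,
                                   slope = slope))
  # stimulating electrodes: spread across the array interior
  stim_ids <- vapply(seq_len(n_stim), function(s) {
    r <- floor(rows * (s / (n_stim + 1)))
    arr$ids[r * cols + floor(cols / 2)]
  }, integer(1))

  pairs <- list(); calls_all <- list(); kfold_spread <- NULL
  for (s in seq_along(stim_ids)) {
    stim <- stim_ids[s]
    art_truth <- gen_artifact_truth(arr, stim, T = fx$T_rec)
    ds <- gen_stim_dataset(arr, fx$eis, art_truth, protocol, truth,
                           noise = noise_model(noise_std),
                           stim_electrode = stim, T = fx$T_rec,
                           seed = seed + 100L * s)
    rec <- ds$recording
    fit_amps <- fitting_amplitudes(protocol$amplitudes, fit_frac)
    averaged <- lapply(fit_amps, function(q) average_trials(rec, q, trim))
    subset <- select_artifact_electrodes(arr, stim, radius)
    art <- fit_artifact_model(averaged, fit_amps, subset, stim, ridge = ridge)
    agg <- assemble(fx$ei_models, art)
    calls <- sort_recording(rec, agg, excluded = "stim", L = L,
                            lambda = lambda, threshold = threshold,
                            latency_range = latency_range)
    calls_all[[s]] <- calls
    for (nid in ids) {
      fit <- fit_sigmoid(build_activation_curve(calls, nid, stim))
      pairs[[length(pairs) + 1]] <- data.frame(
        stim_electrode = stim, neuron_id = nid,
        q50_true = q50_true[match(nid, ids)], q50_est = fit$q50,
        converged = fit$converged)
    }
    if (s == 1 && kfold_K >= 2) {
      kf <- kfold_activation(rec, arr, fx$ei_models, K = kfold_K,
                             seed = seed, radius = radius, trim = trim,
                             fit_frac = fit_frac, ridge = ridge,
                             excluded = "stim", L = L, lambda = lambda,
                             threshold = threshold,
                             latency_range = latency_range)
      kfold_spread <- do.call(rbind, lapply(ids, function(nid) {
        q50s <- kf$fold_thresholds$q50[kf$fold_thresholds$neuron_id == nid]
        data.frame(neuron_id = nid,
                   spread = (max(q50s) - min(q50s)) / q50_true[match(nid, ids)])
      }))
    }
  }
  pairs <- do.call(rbind, pairs)
  cmp <- compare_thresholds(pairs$q50_true, pairs$q50_est)
  rel_err <- abs(pairs$q50_est - pairs$q50_true) / pairs$q50_true
  list(pairs = pairs, r2 = cmp$r2,
       median_rel_err = stats::median(rel_err, na.rm = TRUE),
       kfold_spread = kfold_spread, calls = calls_all)
}

#' Identification round trips on model-generated data
#'
#' Simulates data from randomly drawn stable state-space models and refits
#' them: because the states are directly observed, the regression recovers
#' the trajectory exactly (to round-off) whenever the data are
#' identifiable, giving SNRMSE / ANRMSE at machine precision.
#'
#' @param seed draw seed.
#' @param m state dimension.
#' @param E array size of the embedded model.
#' @param T trajectory length.
#' @param amplitudes artifact amplitudes to check (artifact round trip).
#' @return list with `ei_snrmse`, `artifact_anrmse` (vector, one per
#'   amplitude) and `linearity_err` (max relative deviation of the 2q
#'   output from twice the q output).
#' @export
identification_roundtrip <- function(seed = 1, m = 5, E = 30, T = 60,
                                     amplitudes = c(0.5, 1, 2)) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stable <- function(m) {
    A <- matrix(stats::rnorm(m * m), m)
    A * (0.8 / spectral_radius(A))
  }
  # EI round trip
  pulses <- matrix(0, 2, T); pulses[1, 6] <- 1; pulses[2, 12] <- 1
  tmpl <- input_template(pulses, c(5L, 11L), "ei")
  subset <- sort(sample(0:(E - 1), m))
  true_ei <- state_space_model(stable(m), matrix(stats::rnorm(2 * m), m),
                               subset, tmpl, "ei", id = 0L, n_electrodes = E)
  y <- simulate_lds(true_ei, pulses)
  ei <- electrical_image(0L, y)
  refit <- fit_ei_model(ei, subset, tmpl, ridge = 0)
  ei_snrmse <- snrmse(ei, simulate_lds(refit, pulses), subset)

  # artifact round trip, pooled over amplitudes, linear in q
  ap <- matrix(0, 3, T); ap[cbind(1:3, 1:3)] <- c(1, 0.6, 0.3)
  atmpl <- input_template(ap, 0:2, "artifact")
  stim <- setdiff(0:(E - 1), subset)[1]
  asub <- sort(sample(setdiff(0:(E - 1), stim), m))
  true_art <- state_space_model(stable(m), matrix(stats::rnorm(3 * m), m),
                                asub, atmpl, "artifact", id = stim,
                                n_electrodes = E)
  averaged <- lapply(amplitudes, function(q) simulate_lds(true_art, q * ap))
  arefit <- fit_artifact_model(averaged, amplitudes, asub, stim,
                               template = atmpl, ridge = 0)
  artifact_anrmse <- vapply(seq_along(amplitudes), function(j)
    anrmse(averaged[[j]], simulate_lds(arefit, amplitudes[j] * ap), asub),
    numeric(1))
  y1 <- simulate_lds(arefit, amplitudes[1] * ap)
  y2 <- simulate_lds(arefit, 2 * amplitudes[1] * ap)
  linearity_err <- max(abs(y2 - 2 * y1)) / max(abs(y1))
  list(ei_snrmse = ei_snrmse, artifact_anrmse = artifact_anrmse,
       linearity_err = linearity_err)
}

#' ANRMSE of the artifact model across the amplitude grid
#'
#' Generates a spike-free stimulation dataset with a fixed noise floor over
#' the full log-spaced amplitude grid, fits the artifact model on the
#' lower-amplitude trial averages, and evaluates the ANRMSE against the
#' measured average at every amplitude. At low amplitudes the artifact is
#' small and noise dominates the normalised error; it shrinks as the
#' artifact grows.
#'
#' @param seed dataset seed.
#' @param rows,cols array size.
#' @param noise_std noise floor (uV).
#' @param protocol a [stim_protocol].
#' @param radius,trim,fit_frac,ridge artifact-fit parameters.
#' @return data frame `amplitude_uA, anrmse` over the full grid, with the
#'   Spearman correlation in attribute `"spearman"`.
#' @export
anrmse_trend_study <- function(seed = 1, rows = 12, cols = 12,
                               noise_std = 1, protocol = stim_protocol(),
                               radius = Inf, trim = 0.1, fit_frac = 0.5,
                               ridge = 0) {
  arr <- build_grid_geometry(rows, cols)
  stim <- arr$ids[floor(rows / 2) * cols + floor(cols / 2)]
  art_truth <- gen_artifact_truth(arr, stim, T = 55)
  truth <- ground_truth(data.frame(neuron_id = 0L, q50_uA = Inf, slope = 0.1))
  ei0 <- list()  # spike-free: no neurons at all
  amps <- protocol$amplitudes
  ds <- gen_stim_dataset(arr, ei0, art_truth, protocol,
                         ground_truth(data.frame(neuron_id = integer(0),
                                                 q50_uA = numeric(0),
                                                 slope = numeric(0))),
                         noise = noise_model(noise_std),
                         stim_electrode = stim, T = 55, seed = seed)
  rec <- ds$recording
  fit_amps <- fitting_amplitudes(amps, fit_frac)
  averaged_fit <- lapply(fit_amps, function(q) average_trials(rec, q, trim))
  subset <- select_artifact_electrodes(arr, stim, radius)
  art <- fit_artifact_model(averaged_fit, fit_amps, subset, stim,
                            ridge = ridge)
  tmpl <- art$template
  err <- vapply(amps, function(q) {
    meas <- average_trials(rec, q, trim)
    anrmse(meas, simulate_lds(art, q * tmpl$pulses), subset)
  }, numeric(1))
  out <- data.frame(amplitude_uA = amps, anrmse = err)
  attr(out, "spearman") <- stats::cor(amps, err, method = "spearman")
  out
}
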