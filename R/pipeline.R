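#' Default pipeline configuration
#'
#' All tunable hyperparameters of the pipeline in one place. Values can be
#' overridden by a named list or a YAML file with the same keys.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    rows = 12, cols = 12, pitch = 60,
    n_neurons = 5,
    stim_electrode = NULL,          # NULL: array centre
    T_ei = 71, T_rec = 55,
    noise_std = 1,
    q50_range = c(0.3, 2.5), activation_slope = 0.1,
    n_amplitudes = 39, amp_lo = 0.1, amp_hi = 4.1, repeats = 25,
    frac_threshold = 0.1, abs_threshold = 0, ridge_ei = 0,
    radius = 500, trim = 0.25, fit_frac = 0.25, ridge_artifact = 0,
    L = 10, lambda = 1e-2, theta = 0.5, latency_lo = 0, latency_hi = 30,
    kfold_K = 5)
}

load_config <- function(config = NULL) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(config)] <- config
  }
  cfg
}

#' Run the full synthetic spike-sorting pipeline
#'
#' Executes simulate -> fit-ei -> fit-artifact -> estimate -> sort ->
#' activation on one synthetic dataset and writes every artifact (geometry
#' CSV, EI/recording/model HDF5 containers, spike-call and threshold CSVs,
#' a JSON summary with per-stage metrics and the config) into `out_dir`.
#' Identical config and seed reproduce every output.
#'
#' @param config named list or YAML file path overriding
#'   [default_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the summary list.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("dynsort_run_")) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arr <- build_grid_geometry(cfg$rows, cfg$cols, cfg$pitch)
  stim <- if (is.null(cfg$stim_electrode))
    arr$ids[floor(cfg$rows / 2) * cfg$cols + floor(cfg$cols / 2)]
  else as.integer(cfg$stim_electrode)

  fx <- demo_models(cfg$seed, rows = cfg$rows, cols = cfg$cols,
                    pitch = cfg$pitch, n_neurons = cfg$n_neurons,
                    stim_electrode = stim, T_ei = cfg$T_ei,
                    T_rec = cfg$T_rec, ridge_ei = cfg$ridge_ei,
                    with_artifact = FALSE)
  ids <- vapply(fx$eis, function(e) as.integer(e$neuron_id), integer(1))
  q50_true <- exp(seq(log(cfg$q50_range[1]), log(cfg$q50_range[2]),
                      length.out = cfg$n_neurons))
  protocol <- stim_protocol(
    gen_amplitude_grid(cfg$n_amplitudes, cfg$amp_lo, cfg$amp_hi),
    repeats = cfg$repeats)
  truth <- ground_truth(data.frame(neuron_id = ids, q50_uA = q50_true,
                                   slope = cfg$activation_slope))
  art_truth <- gen_artifact_truth(arr, stim, T = cfg$T_rec)
  ds <- gen_stim_dataset(arr, fx$eis, art_truth, protocol, truth,
                         noise = noise_model(cfg$noise_std),
                         stim_electrode = stim, T = cfg$T_rec,
                         seed = cfg$seed)
  rec <- ds$recording

  # artifact identification on low-contamination amplitudes
  fit_amps <- fitting_amplitudes(protocol$amplitudes, cfg$fit_frac)
  averaged <- lapply(fit_amps, function(q) average_trials(rec, q, cfg$trim))
  subset <- select_artifact_electrodes(arr, stim, cfg$radius)
  art <- fit_artifact_model(averaged, fit_amps, subset, stim,
                            ridge = cfg$ridge_artifact)
  agg <- assemble(fx$ei_models, art)

  calls <- sort_recording(rec, agg, excluded = "stim", L = cfg$L,
                          lambda = cfg$lambda, threshold = cfg$theta,
                          latency_range = cfg$latency_lo:cfg$latency_hi)
  thresholds <- do.call(rbind, lapply(ids, function(nid) {
    fit <- fit_sigmoid(build_activation_curve(calls, nid, stim))
    data.frame(neuron_id = nid, stim_electrode = stim, q50_uA = fit$q50,
               slope = fit$slope, converged = fit$converged)
  }))
  acc <- sorting_accuracy(calls, ds$truth$spikes)
  cmp <- tryCatch(compare_thresholds(q50_true, thresholds$q50_uA),
                  error = function(e) list(r2 = NA_real_))

  # artifacts on disk
  write_geometry_csv(arr, file.path(out_dir, "geometry.csv"))
  write_eis_h5(fx$eis, file.path(out_dir, "eis.h5"))
  write_recording_h5(rec, file.path(out_dir, "recording.h5"))
  write_models_h5(c(fx$ei_models, list(art)), file.path(out_dir, "models.h5"))
  utils::write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
  utils::write.csv(thresholds, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$truth$spikes, file.path(out_dir, "true_spikes.csv"),
                   row.names = FALSE)

  summary <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    snrmse = data.frame(
      neuron_id = ids,
      snrmse = vapply(fx$ei_models, function(m) m$fit$snrmse, numeric(1))),
    anrmse = art$fit$anrmse,
    sorting_accuracy = acc$accuracy,
    thresholds = thresholds,
    q50_true = q50_true,
    threshold_r2 = cmp$r2)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
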