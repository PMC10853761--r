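#' HDF5 container I/O
#'
#' Readers and writers for the package's on-disk containers:
#' \itemize{
#'   \item EIs: dataset `/eis` shaped neurons x electrodes x time (float64,
#'     microvolts), dataset `/neuron_ids`, attribute `sampling_rate_hz`.
#'   \item Recordings: dataset `/data` shaped trials x time x electrodes,
#'     dataset `/amplitudes_uA`, attributes `stim_electrode` and
#'     `sampling_rate_hz`.
#'   \item Models: one HDF5 group per model under `/models`, holding `A`,
#'     `B`, `electrode_subset`, `template_pulses`, `template_times` and
#'     attributes `role`, `id`, `n_electrodes`.
#' }
#'
#' @param path HDF5 file path.
#' @param eis list of [electrical_image] objects.
#' @name dynsort-hdf5
NULL

h5_attr <- function(path, obj, name, value) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, oid, name)
}

read_h5_attr <- function(path, obj, name) {
  a <- rhdf5::h5readAttributes(path, obj)
  a[[name]]
}

#' @rdname dynsort-hdf5
#' @export
write_eis_h5 <- function(eis, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  E <- nrow(eis[[1]]$voltages); T <- ncol(eis[[1]]$voltages)
  arr <- base::array(0, c(length(eis), E, T))
  for (i in seq_along(eis)) arr[i, , ] <- eis[[i]]$voltages
  suppressMessages(rhdf5::h5write(arr, path, "eis"))
  rhdf5::h5write(vapply(eis, function(e) as.integer(e$neuron_id), integer(1)),
                 path, "neuron_ids")
  h5_attr(path, "eis", "sampling_rate_hz", eis[[1]]$sampling_rate)
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname dynsort-hdf5
#' @export
read_eis_h5 <- function(path) {
  arr <- rhdf5::h5read(path, "eis")
  ids <- rhdf5::h5read(path, "neuron_ids")
  rate <- as.numeric(read_h5_attr(path, "eis", "sampling_rate_hz"))
  rhdf5::h5closeAll()
  lapply(seq_along(ids), function(i)
    electrical_image(ids[i], arr[i, , ], sampling_rate = rate))
}

#' @rdname dynsort-hdf5
#' @param rec a [recording].
#' @export
write_recording_h5 <- function(rec, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  suppressMessages(rhdf5::h5write(rec$data, path, "data"))
  rhdf5::h5write(rec$amplitudes, path, "amplitudes_uA")
  h5_attr(path, "data", "stim_electrode", rec$stim_electrode)
  h5_attr(path, "data", "sampling_rate_hz", rec$sampling_rate)
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname dynsort-hdf5
#' @export
read_recording_h5 <- function(path) {
  dat <- rhdf5::h5read(path, "data")
  amps <- as.numeric(rhdf5::h5read(path, "amplitudes_uA"))
  stim <- as.integer(read_h5_attr(path, "data", "stim_electrode"))
  rate <- as.numeric(read_h5_attr(path, "data", "sampling_rate_hz"))
  rhdf5::h5closeAll()
  recording(dat, amps, stim, rate)
}

#' @rdname dynsort-hdf5
#' @param models list of [state_space_model] objects.
#' @export
write_models_h5 <- function(models, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "models")
  for (i in seq_along(models)) {
    m <- models[[i]]
    g <- sprintf("models/%s_%s", m$role, format(m$id))
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(m$A, path, file.path(g, "A"))
    rhdf5::h5write(m$B, path, file.path(g, "B"))
    rhdf5::h5write(m$electrode_subset, path, file.path(g, "electrode_subset"))
    rhdf5::h5write(m$template$pulses, path, file.path(g, "template_pulses"))
    rhdf5::h5write(m$template$pulse_times, path, file.path(g, "template_times"))
    h5_attr(path, g, "role", m$role)
    h5_attr(path, g, "id", as.integer(m$id))
    h5_attr(path, g, "n_electrodes", m$n_electrodes)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname dynsort-hdf5
#' @export
read_models_h5 <- function(path) {
  groups <- rhdf5::h5ls(path)
  gnames <- groups$name[groups$group == "/models" & groups$otype == "H5I_GROUP"]
  models <- lapply(gnames, function(g) {
    pre <- file.path("models", g)
    role <- as.character(read_h5_attr(path, pre, "role"))
    id <- as.integer(read_h5_attr(path, pre, "id"))
    nE <- as.integer(read_h5_attr(path, pre, "n_electrodes"))
    tmpl <- input_template(rhdf5::h5read(path, file.path(pre, "template_pulses")),
                           rhdf5::h5read(path, file.path(pre, "template_times")),
                           role = role)
    state_space_model(rhdf5::h5read(path, file.path(pre, "A")),
                      rhdf5::h5read(path, file.path(pre, "B")),
                      as.integer(rhdf5::h5read(path, file.path(pre, "electrode_subset"))),
                      tmpl, role = role, id = id, n_electrodes = nE)
  })
  rhdf5::h5closeAll()
  models
}
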