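#' Compose EI models and an artifact model into the aggregate system
#'
#' Block-diagonal stacking of N EI models (ordered by ascending neuron id)
#' and, optionally, one artifact model (last): the aggregate state is the
#' concatenation of all sub-model states, the EI inputs stack to a `2N`
#' channel input, the artifact keeps its own 3-channel input, and the output
#' on each electrode is the sum of the contributions of every sub-model that
#' includes it (superposition).
#'
#' @param ei_models list of [state_space_model] objects with role `"ei"`.
#' @param artifact a [state_space_model] with role `"artifact"`, or `NULL`.
#' @return an object of class `aggregate_model` with dense `A`, `B`
#'   (EI-input map, `m x 2N`), `Bp` (artifact-input map, `m x 3` or `NULL`),
#'   `C` (output map, `E x m`) and per-sub-model state/input `slices`.
#' @export
assemble <- function(ei_models, artifact = NULL) {
  if (length(ei_models) == 0 && is.null(artifact))
    stop("need at least one sub-model")
  stopifnot(all(vapply(ei_models, function(m) m$role == "ei", logical(1))))
  if (!is.null(artifact)) stopifnot(artifact$role == "artifact")
  ids <- vapply(ei_models, function(m) as.integer(m$id), integer(1))
  ei_models <- ei_models[order(ids)]
  models <- c(ei_models, if (!is.null(artifact)) list(artifact))
  E <- unique(vapply(models, function(m) m$n_electrodes, integer(1)))
  if (length(E) != 1)
    stop("sub-models disagree on the number of electrodes")
  N <- length(ei_models)
  sizes <- vapply(models, function(m) length(m$electrode_subset), integer(1))
  m_tot <- sum(sizes)
  A <- matrix(0, m_tot, m_tot)
  B <- matrix(0, m_tot, 2L * N)
  Bp <- if (!is.null(artifact)) matrix(0, m_tot, 3L) else NULL
  C <- matrix(0, E, m_tot)
  slices <- vector("list", length(models))
  off <- 0L
  for (i in seq_along(models)) {
    mod <- models[[i]]
    si <- off + seq_len(sizes[i])
    A[si, si] <- mod$A
    if (mod$role == "ei") {
      ui <- 2L * (i - 1L) + 1:2
      B[si, ui] <- mod$B
    } else {
      ui <- 1:3
      Bp[si, ] <- mod$B
    }
    C[cbind(mod$electrode_subset + 1L, si)] <- 1
    slices[[i]] <- list(role = mod$role, id = mod$id, states = si,
                        inputs = ui)
    off <- off + sizes[i]
  }
  structure(
    list(A = A, B = B, Bp = Bp, C = C, slices = slices,
         models = models, n_neurons = N, n_electrodes = E,
         has_artifact = !is.null(artifact)),
    class = "aggregate_model")
}

#' @export
print.aggregate_model <- function(x, ...) {
  cat(sprintf("<aggregate_model> %d EI models%s: %d states, %d electrodes\n",
              x$n_neurons, if (x$has_artifact) " + artifact" else "",
              nrow(x$A), x$n_electrodes))
  invisible(x)
}

neuron_ids <- function(agg) {
  vapply(agg$models[seq_len(agg$n_neurons)], function(m) as.integer(m$id),
         integer(1))
}

#' Simulate the aggregate model
#'
#' Iterates the aggregate recursion from zero initial state and adds i.i.d.
#' Gaussian output noise.
#'
#' @param agg an [aggregate_model].
#' @param ei_inputs `2N x T` EI-input matrix (neuron blocks in ascending-id
#'   order), or `NULL` for all-zero.
#' @param artifact_input `3 x T` artifact-input matrix (`q * template`), or
#'   `NULL`.
#' @param noise a [noise_model] or `NULL` for noiseless output.
#' @param seed integer seed for the noise draw.
#' @return an `E x T` output matrix.
#' @export
simulate_aggregate <- function(agg, ei_inputs = NULL, artifact_input = NULL,
                               noise = NULL, seed = NULL) {
  T_sim <- max(if (!is.null(ei_inputs)) ncol(ei_inputs) else 0L,
               if (!is.null(artifact_input)) ncol(artifact_input) else 0L)
  if (T_sim == 0) stop("no inputs given")
  if (is.null(ei_inputs)) ei_inputs <- matrix(0, ncol(agg$B), T_sim)
  if (nrow(ei_inputs) != ncol(agg$B))
    stop(sprintf("ei_inputs has %d channels, expected %d",
                 nrow(ei_inputs), ncol(agg$B)))
  if (!is.null(artifact_input) && !agg$has_artifact)
    stop("aggregate has no artifact model")
  if (agg$has_artifact && is.null(artifact_input))
    artifact_input <- matrix(0, 3, T_sim)
  x <- numeric(nrow(agg$A))
  y <- matrix(0, agg$n_electrodes, T_sim)
  for (t in seq_len(T_sim)) {
    y[, t] <- agg$C %*% x
    x <- drop(agg$A %*% x + agg$B %*% ei_inputs[, t])
    if (agg$has_artifact) x <- x + drop(agg$Bp %*% artifact_input[, t])
  }
  if (!is.null(noise) && noise$std > 0) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    y <- y + matrix(stats::rnorm(length(y), sd = noise$std), nrow(y))
  }
  y
}

#' Build aggregate EI inputs from firing neurons' templates
#'
#' Places each firing neuron's two-pulse template into the stacked `2N x T`
#' EI-input matrix, shifted by the given latency.
#'
#' @param agg an [aggregate_model].
#' @param firing integer vector of latencies (samples), named by neuron id;
#'   neurons absent from the vector stay silent. Use an empty vector for no
#'   spikes.
#' @param T number of time samples.
#' @return a `2N x T` input matrix.
#' @export
template_inputs <- function(agg, firing, T) {
  u <- matrix(0, ncol(agg$B), T)
  if (length(firing) == 0) return(u)
  ids <- neuron_ids(agg)
  for (k in seq_along(firing)) {
    nid <- as.integer(names(firing)[k])
    i <- match(nid, ids)
    if (is.na(i)) stop("unknown neuron id: ", nid)
    tmpl <- agg$models[[i]]$template
    shift <- firing[[k]]
    times <- tmpl$pulse_times + shift + 1L         # 1-based columns
    ok <- times >= 1 & times <= T
    rows <- agg$slices[[i]]$inputs
    for (ch in which(ok)) u[rows[ch], times[ch]] <- 1
  }
  u
}

#' Artifact input sequence for a stimulus amplitude
#'
#' `u_a = q * r_a`, padded or truncated to `T` columns.
#'
#' @param artifact_template the artifact [input_template].
#' @param q stimulus amplitude in microamperes.
#' @param T number of time samples.
#' @return a `3 x T` matrix.
#' @export
artifact_inputs <- function(artifact_template, q, T) {
  p <- artifact_template$pulses
  u <- matrix(0, 3, T)
  n <- min(ncol(p), T)
  u[, seq_len(n)] <- q * p[, seq_len(n)]
  u
}
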