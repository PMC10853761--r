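#' Linear state-space model over an electrode subset
#'
#' The model is the discrete-time recursion
#' \deqn{x^{t+1} = A x^t + B u^t, \qquad y^t = C x^t,}
#' where the states are the voltages on a subset of electrodes and `C` is the
#' corresponding selection map: the output is the state on the subset
#' electrodes and exactly zero elsewhere. The same class serves the per-neuron
#' electrical-image model (driven by a two-pulse template) and the
#' stimulation-artifact model (driven by a three-pulse template scaled by the
#' stimulus amplitude, with the stimulating electrode structurally excluded
#' from the states).
#'
#' @param A state-transition matrix, `m x m`.
#' @param B input matrix, `m x P`.
#' @param electrode_subset electrode ids (0-based) of the `m` states.
#' @param template an [input_template] matching `P`.
#' @param role `"ei"` or `"artifact"`.
#' @param id neuron id (EI role) or stimulating-electrode id (artifact role).
#' @param n_electrodes total number of electrodes `E` on the array.
#' @param stability_tol tolerance on the spectral-radius stability check;
#'   a radius above `1 + stability_tol` raises a warning (spikes and
#'   artifacts are transients, so fitted dynamics should be stable).
#' @return an object of class `state_space_model`.
#' @export
state_space_model <- function(A, B, electrode_subset, template,
                              role = c("ei", "artifact"), id,
                              n_electrodes, stability_tol = 0.05) {
  role <- match.arg(role)
  A <- as.matrix(A); B <- as.matrix(B)
  m <- length(electrode_subset)
  stopifnot(nrow(A) == m, ncol(A) == m, nrow(B) == m)
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("A and B must be finite")
  if (any(electrode_subset < 0) || any(electrode_subset >= n_electrodes))
    stop("electrode_subset out of range")
  if (!is.null(template)) {
    stopifnot(inherits(template, "input_template"),
              identical(template$role, role),
              nrow(template$pulses) == ncol(B))
  }
  if (role == "artifact" && id %in% electrode_subset)
    stop("the stimulating electrode must not be a state of the artifact model")
  rho <- spectral_radius(A)
  if (rho > 1 + stability_tol)
    warning(sprintf("fitted dynamics are unstable: spectral radius %.3f", rho))
  structure(
    list(A = A, B = B, electrode_subset = as.integer(electrode_subset),
         template = template, role = role, id = id,
         n_electrodes = as.integer(n_electrodes), spectral_radius = rho),
    class = "state_space_model")
}

spectral_radius <- function(A) {
  if (length(A) == 0) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf("<state_space_model> role %s (%s %s): %d states / %d electrodes, spectral radius %.3f\n",
              x$role, if (x$role == "ei") "neuron" else "stim electrode",
              format(x$id), length(x$electrode_subset), x$n_electrodes,
              x$spectral_radius))
  invisible(x)
}

#' Simulate a linear state-space model
#'
#' Iterates `x^{t+1} = A x^t + B u^t`, `y^t = C x^t` for `ncol(inputs)`
#' steps. Output rows outside the model's electrode subset are exactly zero.
#'
#' @param model a [state_space_model].
#' @param inputs input matrix, `P x T`.
#' @param x0 initial state (default zero).
#' @param n_out number of output rows `E` (defaults to the model's array
#'   size).
#' @return an `E x T` output matrix in microvolts.
#' @export
simulate_lds <- function(model, inputs, x0 = NULL, n_out = model$n_electrodes) {
  inputs <- as.matrix(inputs)
  if (nrow(inputs) != ncol(model$B))
    stop(sprintf("input has %d channels but B expects %d",
                 nrow(inputs), ncol(model$B)))
  m <- nrow(model$A)
  if (is.null(x0)) x0 <- numeric(m)
  if (length(x0) != m) stop("x0 must have length ", m)
  T_sim <- ncol(inputs)
  rows <- model$electrode_subset + 1L
  y <- matrix(0, n_out, T_sim)
  x <- as.numeric(x0)
  for (t in seq_len(T_sim)) {
    y[rows, t] <- x
    x <- drop(model$A %*% x + model$B %*% inputs[, t])
  }
  y
}
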