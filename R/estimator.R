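#' Build the windowed response operators of the aggregate model
#'
#' Over a forward window of `L` steps the aggregate output stacks as
#' `y^{t:t+L} = Phi x^t + G u^{t:t+L-1} + H u_a^{t:t+L-1}` where `Phi`
#' holds the free-response maps `C A^k`, and `G` (EI inputs) and `H`
#' (artifact inputs) hold the forced-response maps `C A^{k-1-j} B` (no
#' direct feedthrough: the `k = 0` block row of `G` and `H` is zero). Rows
#' belonging to excluded (corrupted) electrodes are deleted.
#'
#' @param agg an [aggregate_model].
#' @param L window length in samples (>= 1).
#' @param excluded integer vector of corrupted electrode ids to drop
#'   (typically the stimulating electrode), or empty.
#' @return a list of class `window_operator` with `Phi`
#'   (`(L+1)K x m`), `G` (`(L+1)K x 2NL`), `H` (`(L+1)K x 3L` or `NULL`),
#'   `keep` (kept electrode ids) and `L`; `K` is the number of kept
#'   electrodes. Fails if the current-step EI-input block of `G` does not
#'   have full column rank `2N`, naming the unidentifiable neurons.
#' @export
build_window_operator <- function(agg, L = 10, excluded = integer(0)) {
  if (L < 1) stop("L must be >= 1")
  keep <- setdiff(seq_len(agg$n_electrodes) - 1L, as.integer(excluded))
  Ck <- agg$C[keep + 1L, , drop = FALSE]
  K <- nrow(Ck); m <- nrow(agg$A)
  nu <- ncol(agg$B)
  # CAk[[k+1]] = C A^k on kept rows, k = 0..L
  CAk <- vector("list", L + 1)
  CAk[[1]] <- Ck
  for (k in seq_len(L)) CAk[[k + 1]] <- CAk[[k]] %*% agg$A
  Phi <- do.call(rbind, CAk)
  CABs <- lapply(CAk[seq_len(L)], function(M) M %*% agg$B)   # C A^j B
  G <- matrix(0, (L + 1) * K, nu * L)
  H <- if (agg$has_artifact) matrix(0, (L + 1) * K, 3L * L) else NULL
  if (agg$has_artifact)
    CABp <- lapply(CAk[seq_len(L)], function(M) M %*% agg$Bp)
  for (j in seq_len(L)) {               # input at window step j-1
    cols <- (j - 1) * nu + seq_len(nu)
    for (k in j:L) {                    # affects outputs k >= j
      rows <- k * K + seq_len(K)
      G[rows, cols] <- CABs[[k - j + 1]]
      if (agg$has_artifact)
        H[rows, (j - 1) * 3 + 1:3] <- CABp[[k - j + 1]]
    }
  }
  Gc <- G[, seq_len(nu), drop = FALSE]
  r <- qr(Gc)$rank
  if (r < nu) {
    ids <- neuron_ids(agg)
    bad <- ids[vapply(seq_along(ids), function(i) {
      qr(Gc[, 2 * (i - 1) + 1:2, drop = FALSE])$rank < 2
    }, logical(1))]
    stop(sprintf(
      "EI inputs are not identifiable from the kept electrodes (rank %d < %d)%s",
      r, nu,
      if (length(bad)) paste0("; degenerate neurons: ",
                              paste(bad, collapse = ", ")) else ""))
  }
  structure(list(Phi = Phi, G = G, H = H, keep = keep, L = L,
                 n_inputs = nu), class = "window_operator")
}

# Ridge solver for the window least squares; returns the map from the
# window residual to the current-step input estimate (first nu rows kept).
window_solver <- function(op, lambda) {
  p <- ncol(op$G)
  M <- crossprod(op$G) + lambda * diag(p)
  if (lambda == 0) {
    r <- qr(op$G)$rank
    if (r < p)
      stop(sprintf(
        "window input map is rank deficient (%d < %d) with lambda = 0; use lambda > 0",
        r, p))
  }
  S <- solve(M, t(op$G))
  S[seq_len(op$n_inputs), , drop = FALSE]
}

#' Estimate the EI inputs that produced a measured trace
#'
#' Receding-horizon inversion of the aggregate model (the unknown-input
#' estimator). For each time step the state is propagated open loop with the
#' already-estimated inputs, the known artifact input is compensated, and
#' the EI inputs over the forward window are solved by regularised least
#' squares on the non-excluded electrodes; only the current step of the
#' window solution is retained.
#'
#' @param y measured `E x T` matrix (one trial).
#' @param agg an [aggregate_model].
#' @param u_a known `3 x T` artifact input (`q * r_a`), or `NULL` when the
#'   aggregate has no artifact model.
#' @param excluded corrupted electrode ids to exclude.
#' @param L forward window length in samples (default 10, i.e. 0.5 ms).
#' @param lambda ridge penalty on the estimated inputs (default `1e-2`);
#'   `lambda = 0` requires a full-rank window input map.
#' @param op optional precomputed [build_window_operator()] result.
#' @return an object of class `input_estimate` with `u_hat` (`2N x T`,
#'   zero for the last `L` steps), `x_hat` (`m x T`), the excluded set,
#'   `L` and `lambda`. Per-neuron blocks of `u_hat` are addressable through
#'   `slices`.
#' @export
estimate_inputs <- function(y, agg, u_a = NULL, excluded = integer(0),
                            L = 10, lambda = 1e-2, op = NULL) {
  y <- as.matrix(y)
  if (!all(is.finite(y))) stop("measurements must be finite")
  T <- ncol(y)
  if (T <= L) stop("need more samples than the window length")
  res <- estimate_inputs_batch(base::array(y, c(nrow(y), T, 1L)), agg, u_a,
                               excluded = excluded, L = L, lambda = lambda,
                               op = op)
  structure(list(u_hat = res$u_hat[, , 1], x_hat = res$x_hat[, , 1],
                 excluded = as.integer(excluded), L = L, lambda = lambda,
                 slices = agg$slices, neuron_ids = neuron_ids(agg)),
            class = "input_estimate")
}

# Batched estimator core: y_arr is E x T x n_trials, all trials sharing the
# same known artifact input. Returns u_hat (2N x T x n) and x_hat.
estimate_inputs_batch <- function(y_arr, agg, u_a = NULL,
                                  excluded = integer(0), L = 10,
                                  lambda = 1e-2, op = NULL, solver = NULL) {
  E <- dim(y_arr)[1]; T <- dim(y_arr)[2]; n <- dim(y_arr)[3]
  if (is.null(op)) op <- build_window_operator(agg, L, excluded)
  if (is.null(solver)) solver <- window_solver(op, lambda)
  if (agg$has_artifact && is.null(u_a)) u_a <- matrix(0, 3, T)
  K <- length(op$keep)
  yk <- y_arr[op$keep + 1L, , , drop = FALSE]
  nu <- ncol(agg$B)
  u_hat <- base::array(0, c(nu, T, n))
  x_hat <- base::array(0, c(nrow(agg$A), T, n))
  # known-artifact compensation per window start (shared by all trials)
  hua <- NULL
  if (!is.null(op$H)) {
    UA <- vapply(seq_len(T - L), function(t) as.numeric(u_a[, t:(t + L - 1)]),
                 numeric(3 * L))
    hua <- op$H %*% UA                                # rows x (T-L)
  }
  X <- matrix(0, nrow(agg$A), n)
  for (t in seq_len(T - L)) {
    if (t > 1) {
      X <- agg$A %*% X + agg$B %*% u_hat[, t - 1, ]
      if (agg$has_artifact) X <- X + drop(agg$Bp %*% u_a[, t - 1])
    }
    x_hat[, t, ] <- X
    Yw <- matrix(yk[, t:(t + L), , drop = FALSE], nrow = K * (L + 1))
    R <- Yw - op$Phi %*% X
    if (!is.null(hua)) R <- R - hua[, t]
    u_hat[, t, ] <- solver %*% R
  }
  for (t in seq.int(T - L + 1, T)) {     # propagate the tail, inputs zero
    X <- agg$A %*% X + agg$B %*% u_hat[, t - 1, ]
    if (agg$has_artifact) X <- X + drop(agg$Bp %*% u_a[, t - 1])
    x_hat[, t, ] <- X
  }
  list(u_hat = u_hat, x_hat = x_hat, op = op)
}

#' Extract one neuron's block of an input estimate
#'
#' @param estimate an `input_estimate` (or a `2N x T` matrix with the
#'   aggregate's input stacking).
#' @param agg the [aggregate_model] (needed when `estimate` is a matrix).
#' @param neuron_id the neuron.
#' @return the neuron's `2 x T` estimated input.
#' @export
neuron_inputs <- function(estimate, agg = NULL, neuron_id) {
  if (inherits(estimate, "input_estimate")) {
    i <- match(neuron_id, estimate$neuron_ids)
    if (is.na(i)) stop("unknown neuron id: ", neuron_id)
    estimate$u_hat[estimate$slices[[i]]$inputs, , drop = FALSE]
  } else {
    i <- match(neuron_id, neuron_ids(agg))
    if (is.na(i)) stop("unknown neuron id: ", neuron_id)
    estimate[agg$slices[[i]]$inputs, , drop = FALSE]
  }
}

#' Per-neuron RMSE between estimated and true inputs
#'
#' @param estimate an `input_estimate`.
#' @param truth true `2N x T` input matrix (same stacking).
#' @return data frame `neuron_id, rmse` plus an `"overall"` attribute with
#'   the RMSE over the full input matrix.
#' @export
input_rmse <- function(estimate, truth) {
  if (!all(dim(estimate$u_hat) == dim(truth))) stop("shape mismatch")
  ids <- estimate$neuron_ids
  rmse <- vapply(seq_along(ids), function(i) {
    rows <- estimate$slices[[i]]$inputs
    sqrt(mean((estimate$u_hat[rows, ] - truth[rows, ])^2))
  }, numeric(1))
  out <- data.frame(neuron_id = ids, rmse = rmse)
  attr(out, "overall") <- sqrt(mean((estimate$u_hat - truth)^2))
  out
}
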