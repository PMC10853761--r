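#' Build an activation curve for one neuron-electrode pair
#'
#' Aggregates per-trial spike calls into the empirical probability of the
#' neuron firing as a function of the stimulation amplitude, keeping the
#' raw counts for likelihood-based sigmoid fitting.
#'
#' @param calls data frame from [sort_recording()] (columns `neuron_id,
#'   amplitude_uA, detected`).
#' @param neuron_id the neuron.
#' @param stim_electrode stimulating electrode id recorded on the curve.
#' @return an object of class `activation_curve` with `amplitudes`,
#'   `spike_counts`, `trial_counts` and `probabilities`.
#' @export
build_activation_curve <- function(calls, neuron_id, stim_electrode = NA) {
  df <- calls[calls$neuron_id == neuron_id, , drop = FALSE]
  if (nrow(df) == 0) stop("no calls for neuron ", neuron_id)
  amps <- sort(unique(df$amplitude_uA))
  if (length(amps) < 2) stop("need calls at >= 2 amplitudes")
  k <- vapply(amps, function(q) sum(df$detected[df$amplitude_uA == q]), numeric(1))
  n <- vapply(amps, function(q) sum(df$amplitude_uA == q), numeric(1))
  structure(list(neuron_id = neuron_id, stim_electrode = stim_electrode,
                 amplitudes = amps, spike_counts = k, trial_counts = n,
                 probabilities = k / n),
            class = "activation_curve")
}

#' @export
print.activation_curve <- function(x, ...) {
  cat(sprintf("<activation_curve> neuron %s, %d amplitudes, max probability %.2f\n",
              format(x$neuron_id), length(x$amplitudes), max(x$probabilities)))
  invisible(x)
}

#' Fit a sigmoid to an activation curve and extract the 50% threshold
#'
#' Maximum-likelihood logistic fit on the Bernoulli counts,
#' `p(q) = 1 / (1 + exp(-(log q - log q50) / s))` — logistic on the
#' log-amplitude axis, matching the protocol's log-spaced grid. The
#' stimulation threshold is the amplitude at 50% spiking probability
#' (`q50`); it is reported only when the fit converges, the slope is
#' positive, and the curve actually reaches 50%.
#'
#' @param curve an [build_activation_curve()] result.
#' @return list with `q50` (uA), `slope`, `converged` and `threshold`
#'   (`q50` when defined, else `NA`). Degenerate all-0 / all-1 curves give
#'   `converged = FALSE` without an error.
#' @export
fit_sigmoid <- function(curve) {
  k <- curve$spike_counts; n <- curve$trial_counts; q <- curve$amplitudes
  if (length(q) < 2) stop("need >= 2 amplitudes")
  if (sum(k) == 0 || all(k == n))
    return(list(q50 = NA_real_, slope = NA_real_, converged = FALSE,
                threshold = NA_real_))
  fit <- tryCatch(
    suppressWarnings(stats::glm(cbind(k, n - k) ~ log(q),
                                family = stats::binomial(),
                                control = list(maxit = 100))),
    error = function(e) NULL)
  # quasi-separated curves (e.g. a perfect step) stop at the iteration cap
  # with finite coefficients whose ratio — the 50% point — is well defined,
  # so usability is judged on the coefficients, not the IRLS flag
  if (is.null(fit) || !all(is.finite(stats::coef(fit))))
    return(list(q50 = NA_real_, slope = NA_real_, converged = FALSE,
                threshold = NA_real_))
  b <- stats::coef(fit)
  if (b[2] <= 0)
    return(list(q50 = NA_real_, slope = NA_real_, converged = FALSE,
                threshold = NA_real_))
  q50 <- exp(-b[1] / b[2])
  slope <- 1 / b[2]
  ok <- max(curve$probabilities) >= 0.5 && is.finite(q50)
  list(q50 = unname(q50), slope = unname(slope), converged = TRUE,
       threshold = if (ok) unname(q50) else NA_real_)
}

#' Stratified K-fold split of a recording's trials
#'
#' Each amplitude's trials are split as evenly as possible across the K
#' folds (after a seeded shuffle), so every fold covers the whole amplitude
#' grid; folds are disjoint and cover all trials.
#'
#' @param rec a [recording].
#' @param K number of folds (>= 2; every amplitude needs >= K trials).
#' @param seed shuffle seed.
#' @return list of K sorted integer vectors of 1-based trial indices.
#' @export
kfold_split <- function(rec, K = 5, seed = 1) {
  if (K < 2) stop("K must be >= 2")
  folds <- vector("list", K)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (q in unique(rec$amplitudes)) {
    idx <- which(rec$amplitudes == q)
    if (length(idx) < K)
      stop(sprintf("amplitude %g has %d trials, fewer than K = %d",
                   q, length(idx), K))
    idx <- sample(idx)
    f <- rep(seq_len(K), length.out = length(idx))
    for (i in seq_len(K)) folds[[i]] <- c(folds[[i]], idx[f == i])
  }
  lapply(folds, sort)
}

#' K-fold artifact validation of the spike-sorting pipeline
#'
#' For every fold, the artifact model is refitted on the other K-1 folds'
#' trials (trial-averaged over the low-contamination amplitudes), and
#' estimation plus detection run on the held-out fold only — so every
#' activation probability is computed from data unseen by the artifact
#' model that processed it. Returns per-fold curves and thresholds plus the
#' pooled curve over all trials.
#'
#' @param rec a [recording].
#' @param array the [electrode_array].
#' @param ei_models list of fitted EI [state_space_model]s.
#' @param K number of folds.
#' @param seed fold-split seed.
#' @param radius artifact state-electrode radius (um).
#' @param trim trial-average trim fraction.
#' @param fit_frac fraction of the amplitude grid (from the low end) used to
#'   fit the artifact model.
#' @param ridge artifact-model ridge penalty.
#' @param excluded,L,lambda,threshold,latency_range passed to
#'   [sort_recording()].
#' @return list with `fold_thresholds` (data frame `fold, neuron_id, q50,
#'   converged`), `pooled_curves` (list of [build_activation_curve()]
#'   results per neuron), `pooled_thresholds` (data frame) and `calls`
#'   (pooled call table, each trial appearing exactly once).
#' @export
kfold_activation <- function(rec, array, ei_models, K = 5, seed = 1,
                             radius = 150, trim = 0.1, fit_frac = 0.5,
                             ridge = 0, excluded = "stim", L = 10,
                             lambda = 1e-2, threshold = 0.5,
                             latency_range = 0:30) {
  folds <- kfold_split(rec, K, seed)
  ids <- vapply(ei_models, function(m) as.integer(m$id), integer(1))
  all_calls <- vector("list", K)
  fold_thr <- vector("list", K)
  for (f in seq_len(K)) {
    train <- subset_trials(rec, sort(unlist(folds[-f])))
    test_idx <- folds[[f]]
    test <- subset_trials(rec, test_idx)
    fit_amps <- fitting_amplitudes(sort(unique(rec$amplitudes)), fit_frac)
    averaged <- lapply(fit_amps, function(q) average_trials(train, q, trim))
    subset <- select_artifact_electrodes(array, rec$stim_electrode, radius)
    art <- fit_artifact_model(averaged, fit_amps, subset, rec$stim_electrode,
                              ridge = ridge)
    agg <- assemble(ei_models, art)
    calls <- sort_recording(test, agg, excluded = excluded, L = L,
                            lambda = lambda, threshold = threshold,
                            latency_range = latency_range)
    calls$trial <- test_idx[calls$trial]      # back to original indices
    calls$fold <- f
    all_calls[[f]] <- calls
    fold_thr[[f]] <- do.call(rbind, lapply(ids, function(nid) {
      fit <- fit_sigmoid(build_activation_curve(calls, nid,
                                                rec$stim_electrode))
      data.frame(fold = f, neuron_id = nid, q50 = fit$q50,
                 converged = fit$converged)
    }))
  }
  calls <- do.call(rbind, all_calls)
  pooled_curves <- lapply(ids, function(nid)
    build_activation_curve(calls, nid, rec$stim_electrode))
  names(pooled_curves) <- as.character(ids)
  pooled_thr <- do.call(rbind, lapply(pooled_curves, function(cv) {
    fit <- fit_sigmoid(cv)
    data.frame(neuron_id = cv$neuron_id, stim_electrode = rec$stim_electrode,
               q50_uA = fit$q50, slope = fit$slope, converged = fit$converged)
  }))
  rownames(pooled_thr) <- NULL
  list(fold_thresholds = do.call(rbind, fold_thr),
       pooled_curves = pooled_curves, pooled_thresholds = pooled_thr,
       calls = calls)
}

#' Compare two sets of stimulation thresholds
#'
#' Coefficient of determination between matched threshold sets, as used to
#' compare algorithmic thresholds with manual analyses. Two conventions are
#' reported: squared Pearson correlation (the default) and the R^2 about
#' the identity line (`1 - SS_res / SS_tot` with residuals taken against
#' `set_a`). Pairs where either threshold is undefined (`NA`) are excluded
#' and counted.
#'
#' @param set_a,set_b numeric vectors of matched thresholds (uA), or data
#'   frames with columns `neuron_id` (+ optional `stim_electrode`) and
#'   `q50_uA`, merged on the pair keys.
#' @return list with `r2` (Pearson), `r2_identity`, `n_pairs` and
#'   `n_excluded`.
#' @export
compare_thresholds <- function(set_a, set_b) {
  if (is.data.frame(set_a)) {
    keys <- intersect(intersect(names(set_a), names(set_b)),
                      c("neuron_id", "stim_electrode"))
    m <- merge(set_a, set_b, by = keys, suffixes = c("_a", "_b"))
    a <- m$q50_uA_a; b <- m$q50_uA_b
  } else {
    stopifnot(length(set_a) == length(set_b))
    a <- as.numeric(set_a); b <- as.numeric(set_b)
  }
  ok <- is.finite(a) & is.finite(b)
  n_excluded <- sum(!ok)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("need >= 2 matched pairs with defined thresholds")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: R^2 undefined")
  list(r2 = stats::cor(a, b)^2,
       r2_identity = 1 - sum((b - a)^2) / sum((a - mean(a))^2),
       n_pairs = length(a), n_excluded = n_excluded)
}
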