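#' Shift-maximised cosine similarity to an input template
#'
#' Compares a neuron's estimated 2-channel input sequence to its template
#' shifted over a range of candidate latencies and returns the best
#' normalised inner product (cosine). The score is bounded in `[-1, 1]`,
#' scale invariant, and equals 1 exactly when the estimate is a (shifted,
#' positively scaled) copy of the template. An all-zero estimate scores 0
#' by convention.
#'
#' @param u_hat_n estimated `2 x T` input of one neuron.
#' @param template the neuron's [input_template].
#' @param latency_range integer vector of candidate shifts in samples
#'   (default 0:30, i.e. 0-1.5 ms at 20 kHz).
#' @param min_norm magnitude floor: estimates whose Frobenius norm is below
#'   this fraction of a unit pulse score 0, extending the all-zero
#'   convention to numerically negligible estimates (the cosine itself is
#'   scale invariant, so without a floor round-off-sized blocks could score
#'   arbitrarily).
#' @return list with `score` and `latency` (the maximising shift; `NA` for
#'   an all-zero or negligible estimate).
#' @export
similarity <- function(u_hat_n, template, latency_range = 0:30,
                       min_norm = 0.1) {
  if (length(latency_range) == 0) stop("latency_range must be non-empty")
  u_hat_n <- as.matrix(u_hat_n)
  T <- ncol(u_hat_n)
  nu <- sqrt(sum(u_hat_n^2))
  if (nu < min_norm) return(list(score = 0, latency = NA_integer_))
  best <- -Inf; best_s <- NA_integer_
  for (s in latency_range) {
    times <- template$pulse_times + s + 1L       # 1-based columns
    ok <- times >= 1 & times <= T
    if (!any(ok)) next
    # template is 1 at (channel, time) pulse positions, 0 elsewhere
    ip <- sum(u_hat_n[cbind(which(ok), times[ok])])
    sc <- ip / (nu * sqrt(sum(ok)))
    if (sc > best) { best <- sc; best_s <- as.integer(s) }
  }
  if (!is.finite(best)) stop("no template shift falls inside the trace")
  list(score = best, latency = best_s)
}

#' Shift-maximised similarity in response space
#'
#' Like [similarity()], but the comparison happens on the model's response:
#' the estimated input block is pushed through the neuron's own state-space
#' model and the cosine is taken between that response and the response to
#' the shifted template, over the model's electrode subset. The windowed
#' least-squares estimator tends to smear a pulse across neighbouring time
#' steps whose response columns are nearly collinear; those smeared
#' estimates produce almost the template's response, so response-space
#' scoring is far more robust to noise than the raw input cosine while
#' still equalling 1 exactly in the noiseless case.
#'
#' @param u_hat_n estimated `2 x T` input of one neuron.
#' @param model the neuron's [state_space_model].
#' @param latency_range candidate shifts in samples.
#' @param min_norm input-magnitude floor below which the score is 0.
#' @param mag_frac amplitude gate: the cosine is attenuated by
#'   `min(1, mag_ratio / mag_frac)` where `mag_ratio` is the energy of the
#'   estimate's response relative to the template's response at the same
#'   latency. A genuine spike carries the template's stereotyped amplitude
#'   (`mag_ratio` near 1), whereas shape-matched leakage from other
#'   neurons' residuals is much weaker; the gate suppresses it without
#'   affecting true spikes. Set to 0 to disable.
#' @param cache optional precomputed shifted-template responses (internal).
#' @return list with `score` and `latency`.
#' @export
similarity_response <- function(u_hat_n, model, latency_range = 0:30,
                                min_norm = 0.1, mag_frac = 0.5,
                                cache = NULL) {
  if (length(latency_range) == 0) stop("latency_range must be non-empty")
  u_hat_n <- as.matrix(u_hat_n)
  T <- ncol(u_hat_n)
  if (sqrt(sum(u_hat_n^2)) < min_norm)
    return(list(score = 0, latency = NA_integer_))
  rows <- model$electrode_subset + 1L
  yh <- simulate_lds(model, u_hat_n)[rows, , drop = FALSE]
  n1 <- sqrt(sum(yh^2))
  if (n1 == 0) return(list(score = 0, latency = NA_integer_))
  if (is.null(cache)) cache <- response_cache_entry(model, latency_range, T)
  sc <- drop(crossprod(cache$S, as.numeric(yh))) / (n1 * cache$norms)
  if (mag_frac > 0)
    sc <- sc * pmin(1, (n1 / cache$norms) / mag_frac)
  sc[cache$norms == 0] <- -Inf
  if (all(!is.finite(sc))) stop("no template shift falls inside the trace")
  best <- which.max(sc)
  list(score = sc[best], latency = as.integer(latency_range[best]))
}

# Shifted template responses of one EI model, vectorised per shift.
response_cache_entry <- function(model, latency_range, T) {
  rows <- model$electrode_subset + 1L
  p <- model$template$pulses
  u <- matrix(0, nrow(p), T)
  n <- min(ncol(p), T)
  u[, seq_len(n)] <- p[, seq_len(n)]
  base <- simulate_lds(model, u)[rows, , drop = FALSE]
  S <- vapply(latency_range, function(s) {
    sh <- matrix(0, nrow(base), T)
    if (s < T) sh[, (s + 1):T] <- base[, seq_len(T - s)]
    as.numeric(sh)
  }, numeric(length(rows) * T))
  list(S = S, norms = sqrt(colSums(S^2)))
}

#' Per-neuron spike calls from an input estimate
#'
#' Scores every neuron's estimated input block against its template with
#' [similarity()]; a spike is called when the score reaches the threshold.
#' At most one spike per neuron per trial is called (the post-stimulus
#' analysis window is shorter than a typical inter-spike interval).
#'
#' @param estimate an `input_estimate` (one trial).
#' @param agg the [aggregate_model] that produced it (holds the templates).
#' @param threshold detection threshold on the similarity score, in
#'   `(0, 1]`.
#' @param latency_range candidate latencies in samples.
#' @param min_norm magnitude floor passed to the similarity function.
#' @param method `"response"` (default) scores with [similarity_response()],
#'   `"input"` with the raw input cosine of [similarity()].
#' @param cache optional precomputed per-neuron template-response cache
#'   (internal, used by [sort_recording()]).
#' @return data frame `neuron_id, detected, latency_samples, score`.
#' @export
detect <- function(estimate, agg, threshold = 0.5, latency_range = 0:30,
                   min_norm = 0.1, method = c("response", "input"),
                   cache = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  method <- match.arg(method)
  ids <- neuron_ids(agg)
  out <- lapply(seq_along(ids), function(i) {
    u_n <- neuron_inputs(estimate, neuron_id = ids[i])
    sim <- if (method == "response") {
      similarity_response(u_n, agg$models[[i]], latency_range, min_norm,
                          cache = cache[[i]])
    } else {
      similarity(u_n, agg$models[[i]]$template, latency_range, min_norm)
    }
    data.frame(neuron_id = ids[i], detected = sim$score >= threshold,
               latency_samples = if (sim$score >= threshold) sim$latency else NA_integer_,
               score = sim$score)
  })
  do.call(rbind, out)
}

#' Run estimation and detection over every trial of a recording
#'
#' The practical spike-sorting driver: builds the window operator once,
#' groups trials by stimulation amplitude (the artifact input `q * r_a` is
#' known per amplitude), runs the batched input estimator, and calls spikes
#' per neuron and trial.
#'
#' @param rec a [recording].
#' @param agg an [aggregate_model] (with an artifact model if the recording
#'   contains stimulation artifact).
#' @param excluded corrupted electrode ids; the default `"stim"` excludes
#'   the recording's stimulating electrode. Use `integer(0)` for none.
#' @param L,lambda estimator window and ridge (see [estimate_inputs()]).
#' @param threshold,latency_range,min_norm,method detection parameters
#'   (see [detect()]).
#' @return data frame `trial, amplitude_uA, neuron_id, detected,
#'   latency_samples, score` (one row per neuron per trial).
#' @export
sort_recording <- function(rec, agg, excluded = "stim", L = 10,
                           lambda = 1e-2, threshold = 0.5,
                           latency_range = 0:30, min_norm = 0.1,
                           method = c("response", "input")) {
  method <- match.arg(method)
  if (identical(excluded, "stim")) excluded <- rec$stim_electrode
  excluded <- as.integer(excluded)
  T <- dim(rec$data)[2]
  op <- build_window_operator(agg, L, excluded)
  solver <- window_solver(op, lambda)
  ids <- neuron_ids(agg)
  cache <- if (method == "response")
    lapply(agg$models[seq_len(agg$n_neurons)], response_cache_entry,
           latency_range = latency_range, T = T)
  tmpl_art <- if (agg$has_artifact)
    agg$models[[length(agg$models)]]$template else NULL
  calls <- vector("list", dim(rec$data)[1])
  for (q in unique(rec$amplitudes)) {
    trials <- which(rec$amplitudes == q)
    y_arr <- aperm(rec$data[trials, , , drop = FALSE], c(3, 2, 1))
    u_a <- if (!is.null(tmpl_art)) artifact_inputs(tmpl_art, q, T) else NULL
    res <- estimate_inputs_batch(y_arr, agg, u_a, excluded = excluded,
                                 L = L, lambda = lambda, op = op,
                                 solver = solver)
    for (j in seq_along(trials)) {
      est <- structure(list(u_hat = res$u_hat[, , j], slices = agg$slices,
                            neuron_ids = ids),
                       class = "input_estimate")
      df <- detect(est, agg, threshold, latency_range, min_norm,
                   method = method, cache = cache)
      df <- cbind(trial = trials[j], amplitude_uA = q, df)
      calls[[trials[j]]] <- df
    }
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Brute-force spike-sorting oracle by exhaustive enumeration
#'
#' Independent verification oracle for small instances: enumerates every
#' subset of at most `max_neurons` neurons and every combination of
#' latencies, simulates the aggregate model for each hypothesis, and
#' returns the hypothesis minimising the penalised residual sum of squares
#' on the non-excluded electrodes. The penalty (`pen_factor * noise_std^2`
#' per spike) is what makes the search consistent on noisy data: an
#' unpenalised minimum always absorbs a little noise with every spurious
#' spike, whereas a genuine spike lowers the residual by its full signal
#' energy, orders of magnitude above the noise projection. With
#' `noise_std = 0` the criterion is the plain residual and exact ties
#' break toward fewer spikes, then lower latencies.
#'
#' @param y measured `E x T` matrix (one trial).
#' @param agg an [aggregate_model].
#' @param u_a known `3 x T` artifact input or `NULL`.
#' @param excluded corrupted electrode ids.
#' @param latency_range candidate latencies (at most 16 values).
#' @param max_neurons maximum hypothesis size (N <= 5 enforced).
#' @param noise_std measurement-noise standard deviation of the data.
#' @param pen_factor per-spike residual penalty in units of the noise
#'   variance.
#' @return list with `neuron_ids`, `latencies` (named by neuron id) and
#'   `rss` of the winning hypothesis.
#' @export
oracle_enumerate <- function(y, agg, u_a = NULL, excluded = integer(0),
                             latency_range = 8:12, max_neurons = NULL,
                             noise_std = 0, pen_factor = 15) {
  ids <- neuron_ids(agg)
  N <- length(ids)
  if (is.null(max_neurons)) max_neurons <- N
  if (N > 5 || length(latency_range) > 16)
    stop("exhaustive search limited to <= 5 neurons and <= 16 latencies")
  T <- ncol(y)
  keep <- setdiff(seq_len(agg$n_electrodes) - 1L, as.integer(excluded)) + 1L
  # artifact-compensated target
  y0 <- y[keep, , drop = FALSE]
  if (agg$has_artifact && !is.null(u_a))
    y0 <- y0 - simulate_aggregate(agg, NULL, u_a)[keep, , drop = FALSE]
  # candidate signals: neuron x latency, on kept electrodes
  nlat <- length(latency_range)
  sig <- vector("list", N * nlat)
  for (i in seq_len(N)) {
    base_u <- template_inputs(agg, stats::setNames(0L, ids[i]), T)
    base_y <- simulate_aggregate(agg, base_u)[keep, , drop = FALSE]
    for (l in seq_len(nlat)) {
      s <- latency_range[l]
      shifted <- matrix(0, length(keep), T)
      if (s < T) shifted[, (s + 1):T] <- base_y[, seq_len(T - s)]
      sig[[(i - 1) * nlat + l]] <- shifted
    }
  }
  smat <- vapply(sig, as.numeric, numeric(length(keep) * T))
  cvec <- drop(crossprod(smat, as.numeric(y0)))
  gram <- crossprod(smat)
  y0ss <- sum(y0^2)

  penalty <- pen_factor * noise_std^2
  best <- list(rss = y0ss, score = y0ss, neuron_ids = integer(0),
               latencies = stats::setNames(integer(0), character(0)))
  tol <- 1e-9 * max(1, y0ss)
  for (k in seq_len(min(max_neurons, N))) {
    combos <- utils::combn(N, k)
    lat_grid <- as.matrix(expand.grid(rep(list(seq_len(nlat)), k)))
    for (ci in seq_len(ncol(combos))) {
      nn <- combos[, ci]
      cand <- t((nn[col(lat_grid)] - 1) * nlat + lat_grid[, seq_len(k)])
      dim(cand) <- c(k, nrow(lat_grid))
      csum <- colSums(matrix(cvec[cand], k))
      gsum <- numeric(ncol(cand))
      for (a in seq_len(k)) for (b in seq_len(k))
        gsum <- gsum + gram[cbind(cand[a, ], cand[b, ])]
      rss <- y0ss - 2 * csum + gsum + k * penalty
      w <- which.min(rss)
      if (rss[w] < best$score - tol) {
        lats <- latency_range[lat_grid[w, ]]
        best <- list(rss = rss[w] - k * penalty, score = rss[w],
                     neuron_ids = ids[nn],
                     latencies = stats::setNames(as.integer(lats),
                                                 as.character(ids[nn])))
      }
    }
  }
  best
}

#' Spike-sorting accuracy against ground truth
#'
#' A trial is correct when the set of detected neurons equals the set of
#' truly evoked neurons. Also reports per-neuron precision and recall.
#'
#' @param calls data frame of calls from [sort_recording()] (columns
#'   `trial, neuron_id, detected`).
#' @param truth_spikes realised-spike data frame (`trial, neuron_id`), e.g.
#'   from [gen_stim_dataset()].
#' @param trials trial indices covered by both (default: all trials in
#'   `calls`).
#' @return list with `accuracy` and a `per_neuron` data frame
#'   (`neuron_id, precision, recall`).
#' @export
sorting_accuracy <- function(calls, truth_spikes, trials = NULL) {
  if (is.null(trials)) trials <- sort(unique(calls$trial))
  if (length(setdiff(truth_spikes$trial, trials)) > 0)
    stop("truth contains trials absent from the calls")
  ids <- sort(unique(calls$neuron_id))
  det <- calls[calls$detected, c("trial", "neuron_id")]
  key <- function(df) paste(df$trial, df$neuron_id)
  correct <- vapply(trials, function(tr) {
    setequal(det$neuron_id[det$trial == tr],
             truth_spikes$neuron_id[truth_spikes$trial == tr])
  }, logical(1))
  tp_keys <- intersect(key(det), key(truth_spikes))
  per <- do.call(rbind, lapply(ids, function(nid) {
    d <- sum(det$neuron_id == nid)
    n_true <- sum(truth_spikes$neuron_id == nid & truth_spikes$trial %in% trials)
    tp <- sum(det$neuron_id == nid & key(det) %in% tp_keys)
    data.frame(neuron_id = nid,
               precision = if (d > 0) tp / d else NA_real_,
               recall = if (n_true > 0) tp / n_true else NA_real_)
  }))
  list(accuracy = mean(correct), per_neuron = per)
}
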