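## SunTag fluorescence signal model: occupancy -> noiseless intensity ->
## lognormal-noisy intensity traces with experiment-like observation windows.

#' Noiseless SunTag intensity from an occupancy trace
#'
#' The epitope signal of a frame is the scalar product of the cumulative
#' epitope weights with the occupancy vector, `n(t) = w . tau(t)`; the
#' noiseless intensity is `b0 + (i_MP / n_S) * n(t)`, so a ribosome that has
#' fully cleared the SunTag contributes exactly `i_MP`.
#'
#' @param occ an `occupancy_trace` or any list with an `n_epitopes` field
#'   (e.g. one element of [simulate_runoff_ensemble()]).
#' @param geom the [reporter_geometry()] used in the simulation.
#' @param noise a [noise_model()].
#' @return Numeric vector of noiseless intensities, one per frame.
#' @export
epitope_signal <- function(occ, geom, noise) {
  stopifnot(inherits(geom, "reporter_geometry"), inherits(noise, "noise_model"))
  if (!is.null(occ$occupancy)) {
    if (ncol(occ$occupancy) != length(geom$w))
      stop("occupancy width does not match the weight vector length")
    nepi <- as.numeric(occ$occupancy %*% geom$w)
  } else if (!is.null(occ$n_epitopes)) {
    nepi <- occ$n_epitopes
  } else {
    stop("occ must carry an occupancy matrix or an n_epitopes field")
  }
  noise$b0 + noise$i_MP / geom$n_S * nepi
}

#' Apply multiplicative lognormal acquisition noise
#'
#' Each frame becomes `y = mu * exp(s0 * X)` with `X` standard normal, so
#' the median of replicate draws equals the noiseless value `mu` and all
#' outputs are strictly positive.
#'
#' @param mu noiseless intensity vector (strictly positive).
#' @param s0 lognormal noise scale.
#' @param seed optional integer seed (calls [set.seed()]).
#' @export
add_lognormal_noise <- function(mu, s0, seed = NULL) {
  stopifnot(all(mu > 0), s0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  mu * exp(s0 * rnorm(length(mu)))
}

#' Sample an observation window for a simulated trace
#'
#' Trace durations mimic single-particle tracking: exponential with mean
#' `mean_duration`, resampled until at least `min_duration` (equivalently
#' `min_duration` plus an exponential tail, by memorylessness).  Run-off
#' traces start at t = 0; steady-state traces get a uniformly random start
#' inside the recording.
#'
#' @param n_frames_available frames available in the source recording.
#' @param dt frame interval, seconds.
#' @param mean_duration,min_duration exponential mean and truncation point,
#'   seconds.
#' @param runoff if `TRUE` the window starts at the first frame.
#' @return A list with integer `start` and `end` frame indices (1-based).
#' @export
sample_trace_window <- function(n_frames_available, dt, mean_duration = 600,
                                min_duration = 300, runoff = TRUE) {
  stopifnot(n_frames_available >= 1, dt > 0, min_duration >= 0)
  duration <- min_duration + rexp(1, rate = 1 / mean_duration)
  n_frames <- floor(duration / dt) + 1
  if (runoff) {
    start <- 1L
  } else {
    start <- sample.int(max(1L, n_frames_available - 1L), 1L)
  }
  end <- min(n_frames_available, start + n_frames - 1L)
  list(start = start, end = as.integer(end))
}

#' Generate an ensemble of noisy run-off intensity traces
#'
#' The full synthetic-data generator: steady-state burn-in of the l-TASEP,
#' run-off per trace, conversion to noiseless SunTag intensity, lognormal
#' noise, and experiment-like observation windows (exponential durations of
#' mean 10 min truncated at 5 min).  A trace whose window ends before the
#' last ribosome has terminated is flagged censored.
#'
#' @param n_traces number of traces.
#' @param geom a [reporter_geometry()].
#' @param params a [kinetic_params()].
#' @param noise a [noise_model()].
#' @param dt frame interval, seconds.
#' @param seed optional integer seed.
#' @param experiment_id,condition labels carried into the output table.
#' @param mean_duration,min_duration observation-window law, seconds.
#' @param window if `FALSE`, keep every simulated frame (no duration
#'   sampling, no censoring by tracking loss).
#' @return A long-format data.frame with columns `trace_id`,
#'   `experiment_id`, `condition`, `t_r`, `time_s`, `intensity`, `censored`,
#'   plus the simulation ground truth `n_true` (number of ribosomes).
#' @export
simulate_runoff_traces <- function(n_traces, geom, params, noise, dt = 20,
                                   seed = NULL, experiment_id = "sim",
                                   condition = "control",
                                   mean_duration = 600, min_duration = 300,
                                   window = TRUE) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  ens <- simulate_runoff_ensemble(geom, params, n_traces, dt = dt)
  out <- vector("list", n_traces)
  for (r in seq_len(n_traces)) {
    tr <- ens[[r]]
    times <- tr$times
    n_rib <- tr$n_ribosomes
    n_epi <- tr$n_epitopes
    if (window) {
      ## tracking continues past run-off completion: the observation window
      ## is set by the tracking-duration law, with baseline frames after the
      ## last termination
      win <- sample_trace_window(.Machine$integer.max, dt, mean_duration,
                                 min_duration, runoff = TRUE)
      n_frames <- win$end - win$start + 1L
      if (n_frames > length(times)) {
        extra <- n_frames - length(times)
        times <- c(times, max(times) + dt * seq_len(extra))
        n_rib <- c(n_rib, integer(extra))
        n_epi <- c(n_epi, numeric(extra))
      } else {
        idx <- seq_len(n_frames)
        times <- times[idx]; n_rib <- n_rib[idx]; n_epi <- n_epi[idx]
      }
    }
    mu <- noise$b0 + noise$i_MP / geom$n_S * n_epi
    y <- add_lognormal_noise(mu, noise$s0)
    censored <- n_rib[length(n_rib)] > 0L
    out[[r]] <- data.frame(
      trace_id = sprintf("%s_%04d", experiment_id, r),
      experiment_id = experiment_id,
      condition = condition,
      t_r = 0,
      time_s = times,
      intensity = y,
      censored = censored,
      n_true = n_rib
    )
  }
  res <- do.call(rbind, out)
  attr(res, "manifest") <- list(
    n_traces = n_traces, L = geom$L, L_S = geom$L_S, n_S = geom$n_S,
    ell = geom$ell, alpha = params$alpha, lam = params$lam,
    b0 = noise$b0, i_MP = noise$i_MP, s0 = noise$s0, dt = dt,
    mean_duration = mean_duration, min_duration = min_duration,
    seed = seed)
  res
}

#' Write / read intensity-trace tables
#'
#' Long-format tab-delimited text with a header; the documented columns are
#' `trace_id`, `experiment_id`, `condition`, `t_r`, `time_s`, `intensity`,
#' `censored` (simulated tables may carry the ground-truth column `n_true`).
#'
#' @param traces a trace data.frame.
#' @param path file path.
#' @export
write_traces <- function(traces, path) {
  write.table(traces, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("trace_id", "time_s", "intensity")
  if (!all(needed %in% names(df)))
    stop("trace table must contain columns: ", paste(needed, collapse = ", "))
  if (is.null(df$t_r)) df$t_r <- 0
  if (is.null(df$censored)) df$censored <- FALSE
  df
}
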