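## Gillespie l-TASEP simulation: R interface over the C++ engine.

occupancy_trace <- function(raw, geom, params, mode) {
  keep <- !is.null(raw$occupancy)
  structure(
    list(times = raw$times,
         n_ribosomes = raw$n_ribosomes,
         n_epitopes = raw$n_epitopes,
         gene_state = raw$gene_state,
         occupancy = if (keep) raw$occupancy else NULL,
         counts = raw$counts,
         geom = geom, params = params, mode = mode),
    class = "occupancy_trace"
  )
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat(sprintf("l-TASEP %s trace: %d frames (dt = %.3g s), %d -> %d ribosomes\n",
              x$mode, length(x$times),
              if (length(x$times) > 1) diff(x$times[1:2]) else NA_real_,
              x$n_ribosomes[1], x$n_ribosomes[length(x$n_ribosomes)]))
  cat("events:", paste(names(x$counts), x$counts, collapse = ", ", sep = " = "),
      "\n")
  invisible(x)
}

check_sim_args <- function(geom, duration, dt, burn_in) {
  stopifnot(inherits(geom, "reporter_geometry"))
  if (dt <= 0) stop("dt must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (burn_in < 0) stop("burn_in must be >= 0")
}

#' Simulate the l-TASEP at steady state
#'
#' Exact event-driven simulation of ribosome traffic on a single transcript.
#' The lattice starts empty, a burn-in of `burn_in` reaction events lets the
#' process relax, and the occupancy state is then recorded every `dt` seconds
#' for `duration` seconds (frames at t = 0, dt, 2*dt, ...).
#'
#' @param geom a [reporter_geometry()].
#' @param params a [kinetic_params()]; telegraph rates are ignored here
#'   (see [simulate_bursting()]).
#' @param duration recorded duration, seconds.
#' @param dt recording interval, seconds.
#' @param burn_in number of reaction events before recording starts.
#' @param keep_occupancy record the full binary occupancy vector per frame
#'   (memory-heavy for long transcripts).
#' @return An `occupancy_trace`: frame times, ribosome counts, epitope signal
#'   `w . tau`, gene state, event counts, and optionally the occupancy matrix.
#' @seealso [simulate_runoff()], [simulate_bursting()]
#' @export
simulate_steady_state <- function(geom, params, duration = 5400, dt = 20,
                                  burn_in = 1000L, keep_occupancy = FALSE) {
  check_sim_args(geom, duration, dt, burn_in)
  raw <- tasep_sim_cpp(geom$L, geom$ell, params$alpha, params$lam,
                       FALSE, 0, 0, as.integer(burn_in), duration, dt,
                       geom$w, FALSE, keep_occupancy)
  occupancy_trace(raw, geom, params, "steady-state")
}

#' Simulate a harringtonine run-off
#'
#' Burn-in at the stated initiation rate seeds the steady-state initial
#' condition; at t = 0 all pending initiation events are purged and the
#' initiation rate is set to zero, so the loaded ribosomes run off the
#' transcript.  Recording stops at the first frame with an empty lattice.
#'
#' @inheritParams simulate_steady_state
#' @return An `occupancy_trace` with non-increasing `n_ribosomes`.
#' @export
simulate_runoff <- function(geom, params, duration = 5400, dt = 20,
                            burn_in = 1000L, keep_occupancy = FALSE) {
  check_sim_args(geom, duration, dt, burn_in)
  raw <- tasep_sim_cpp(geom$L, geom$ell, params$alpha, params$lam,
                       params$telegraph,
                       if (params$telegraph) params$k_on else 0,
                       if (params$telegraph) params$k_off else 0,
                       as.integer(burn_in), duration, dt,
                       geom$w, TRUE, keep_occupancy)
  occupancy_trace(raw, geom, params, "run-off")
}

#' Simulate the l-TASEP with two-state bursty initiation
#'
#' Telegraph extension: the transcript toggles between an inactive state
#' (G = 0, no initiation) with exponential dwell `Exp(k_on)` and an active
#' state (G = 1) with dwell `Exp(k_off)`; initiation proceeds at `alpha` only
#' while active.
#'
#' @inheritParams simulate_steady_state
#' @export
simulate_bursting <- function(geom, params, duration = 5400, dt = 20,
                              burn_in = 1000L, keep_occupancy = FALSE) {
  check_sim_args(geom, duration, dt, burn_in)
  if (!params$telegraph)
    stop("simulate_bursting() requires kinetic_params with k_on and k_off")
  raw <- tasep_sim_cpp(geom$L, geom$ell, params$alpha, params$lam,
                       TRUE, params$k_on, params$k_off,
                       as.integer(burn_in), duration, dt,
                       geom$w, FALSE, keep_occupancy)
  occupancy_trace(raw, geom, params, "bursting")
}

#' Ensemble of run-off occupancy traces
#'
#' One steady-state burn-in is shared by all traces; between consecutive
#' traces the steady-state process advances `decorrelate` reaction events
#' before its state is copied and run off with initiation disabled.  Only the
#' per-frame ribosome count and epitope signal are kept, which makes large
#' ensembles cheap.
#'
#' @inheritParams simulate_steady_state
#' @param n_traces number of run-off traces.
#' @param decorrelate reaction events between consecutive trace snapshots.
#' @return A list of length `n_traces`; each element has `times`,
#'   `n_ribosomes` and `n_epitopes`.
#' @export
simulate_runoff_ensemble <- function(geom, params, n_traces, duration = 5400,
                                     dt = 20, burn_in = 1000L,
                                     decorrelate = 1000L) {
  check_sim_args(geom, duration, dt, burn_in)
  stopifnot(n_traces >= 1)
  runoff_ensemble_cpp(geom$L, geom$ell, params$alpha, params$lam,
                      params$telegraph,
                      if (params$telegraph) params$k_on else 0,
                      if (params$telegraph) params$k_off else 0,
                      as.integer(burn_in), as.integer(decorrelate),
                      as.integer(n_traces), duration, dt, geom$w)
}

#' Ensemble of steady-state occupancy traces
#'
#' @inheritParams simulate_runoff_ensemble
#' @export
simulate_steady_ensemble <- function(geom, params, n_traces, duration = 5400,
                                     dt = 20, burn_in = 1000L,
                                     decorrelate = 1000L) {
  check_sim_args(geom, duration, dt, burn_in)
  stopifnot(n_traces >= 1)
  steady_ensemble_cpp(geom$L, geom$ell, params$alpha, params$lam,
                      params$telegraph,
                      if (params$telegraph) params$k_on else 0,
                      if (params$telegraph) params$k_off else 0,
                      as.integer(burn_in), as.integer(decorrelate),
                      as.integer(n_traces), duration, dt, geom$w)
}

#' Serialize an occupancy trace to a columnar table
#'
#' @param x an `occupancy_trace`.
#' @param trace_id identifier carried into the table.
#' @param ... unused.
#' @return A data.frame with columns `trace_id`, `time_s`, `n_ribosomes`,
#'   `n_epitopes`, `gene_state`.
#' @export
as.data.frame.occupancy_trace <- function(x, trace_id = "trace1", ...) {
  data.frame(trace_id = trace_id, time_s = x$times,
             n_ribosomes = x$n_ribosomes, n_epitopes = x$n_epitopes,
             gene_state = x$gene_state)
}

#' Check the extended-particle exclusion constraint
#'
#' Verifies that no two occupied sites in any recorded frame are closer than
#' the ribosome footprint.
#'
#' @param occ an `occupancy_trace` recorded with `keep_occupancy = TRUE`.
#' @return `TRUE` invisibly; errors if the constraint is violated.
#' @export
check_exclusion <- function(occ) {
  stopifnot(inherits(occ, "occupancy_trace"))
  if (is.null(occ$occupancy))
    stop("trace was recorded without keep_occupancy = TRUE")
  ell <- occ$geom$ell
  for (f in seq_len(nrow(occ$occupancy))) {
    pos <- which(occ$occupancy[f, ] == 1L)
    if (length(pos) > 1L && any(diff(pos) < ell))
      stop(sprintf("exclusion violated in frame %d", f))
  }
  invisible(TRUE)
}
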