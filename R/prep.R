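## Trace preprocessing: noise estimation from translation-arrested traces,
## despiking, filtering rules, burst segmentation and empirical density.

#' Preprocessing configuration
#'
#' @param lowpass_cutoff low-pass cutoff for smoothing, Hz.
#' @param spike_factor spike threshold in multiples of the multiplicative
#'   noise.
#' @param max_start_after_HT latest admissible trace start after drug
#'   addition, seconds.
#' @param min_traces_per_experiment minimum trace count per experiment.
#' @param min_track_length minimal track span, seconds.
#' @param ht_delay delay between drug addition and run-off start, seconds
#'   (trace start offsets `t_r` are measured from run-off start).
#' @export
prep_config <- function(lowpass_cutoff = 1 / 120, spike_factor = 2,
                        max_start_after_HT = 100,
                        min_traces_per_experiment = 10L,
                        min_track_length = 300, ht_delay = 60) {
  stopifnot(lowpass_cutoff > 0, spike_factor > 0, max_start_after_HT > 0,
            min_traces_per_experiment > 0, min_track_length > 0)
  structure(list(lowpass_cutoff = lowpass_cutoff,
                 spike_factor = spike_factor,
                 max_start_after_HT = max_start_after_HT,
                 min_traces_per_experiment = as.integer(min_traces_per_experiment),
                 min_track_length = min_track_length,
                 ht_delay = ht_delay),
            class = "prep_config")
}

## zero-phase order-2 Butterworth low-pass; falls back to a short running
## mean when the trace is too short for stable forward-backward filtering.
## A 3-point running median is applied first so that the smoothing reference
## is robust to the single-frame spikes the despiking step must flag.
lowpass_smooth <- function(y, dt, cutoff, prefilter = TRUE) {
  if (prefilter && length(y) >= 3) y <- stats::runmed(y, 3)
  nyq <- 1 / (2 * dt)
  W <- min(cutoff / nyq, 0.99)
  if (length(y) >= 12) {
    bf <- signal::butter(2, W, type = "low")
    as.numeric(signal::filtfilt(bf, y))
  } else {
    k <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    out <- as.numeric(k)
    out[is.na(out)] <- y[is.na(out)]
    out
  }
}

#' Estimate the multiplicative tracking noise from arrested traces
#'
#' Traces acquired under translation arrest carry no kinetic signal, so
#' their fluctuations measure the acquisition noise.  Per trace, a linear
#' trend (photobleaching) is regressed out and the coefficient of variation
#' of the residual signal around the trace mean is computed; the global
#' noise is the mean CV over traces, and the equivalent lognormal scale is
#' `s0 = sqrt(log(1 + CV^2))`.
#'
#' @param traces long-format trace data.frame of arrested (e.g.
#'   cycloheximide) traces.
#' @return A list with `cv_per_trace`, `noise` (mean CV) and `s0`.
#' @export
estimate_multiplicative_noise <- function(traces) {
  cvs <- vapply(split(traces, traces$trace_id), function(d) {
    d <- d[order(d$time_s), ]
    if (nrow(d) < 3) return(NA_real_)
    fit <- lm(intensity ~ time_s, data = d)
    sd(residuals(fit)) / mean(d$intensity)
  }, 0)
  cvs <- cvs[!is.na(cvs)]
  noise <- mean(cvs)
  list(cv_per_trace = cvs, noise = noise, s0 = sqrt(log1p(noise^2)))
}

#' Despike an intensity trace
#'
#' The trace is smoothed with a zero-phase order-2 Butterworth low-pass
#' filter; frames where the relative difference between raw and smoothed
#' value exceeds `spike_factor` times the multiplicative noise are replaced
#' by the smoothed value, all other frames are untouched.
#'
#' @param y raw intensities.
#' @param dt frame interval, seconds.
#' @param noise multiplicative noise magnitude (CV), e.g. from
#'   [estimate_multiplicative_noise()].
#' @param config a [prep_config()].
#' @return A list with `y` (cleaned), `smooth`, and logical `replaced`.
#' @export
despike <- function(y, dt, noise, config = prep_config()) {
  stopifnot(all(y > 0), noise > 0)
  sm <- lowpass_smooth(y, dt, config$lowpass_cutoff)
  sm <- pmax(sm, .Machine$double.eps)
  rel <- abs(y - sm) / sm
  replaced <- rel > config$spike_factor * noise
  out <- y
  out[replaced] <- sm[replaced]
  list(y = out, smooth = sm, replaced = replaced)
}

#' Filter run-off traces by start time, track length and experiment size
#'
#' Retains traces that start no later than `max_start_after_HT` seconds
#' after drug addition (trace offsets `t_r` count from run-off start,
#' `ht_delay` seconds after the drug) and span at least `min_track_length`
#' seconds; experiments left with fewer than `min_traces_per_experiment`
#' traces are then excluded entirely.  Every exclusion is logged with its
#' rule.
#'
#' @param traces long-format trace data.frame with `experiment_id` and
#'   `t_r` columns.
#' @param config a [prep_config()].
#' @return A list with `traces` (retained rows) and `report` (data.frame of
#'   exclusions: `trace_id`, `experiment_id`, `rule`).
#' @export
filter_runoff_traces <- function(traces, config = prep_config()) {
  stopifnot(all(c("trace_id", "time_s") %in% names(traces)))
  if (is.null(traces$experiment_id)) traces$experiment_id <- "exp1"
  if (is.null(traces$t_r)) traces$t_r <- 0
  info <- do.call(rbind, lapply(split(traces, traces$trace_id), function(d) {
    data.frame(trace_id = d$trace_id[1], experiment_id = d$experiment_id[1],
               t_r = d$t_r[1], span = max(d$time_s) - min(d$time_s))
  }))
  report <- list()
  late <- info$t_r + config$ht_delay > config$max_start_after_HT
  short <- !late & info$span < config$min_track_length
  if (any(late))
    report$late <- data.frame(trace_id = info$trace_id[late],
                              experiment_id = info$experiment_id[late],
                              rule = "start_after_HT")
  if (any(short))
    report$short <- data.frame(trace_id = info$trace_id[short],
                               experiment_id = info$experiment_id[short],
                               rule = "track_length")
  surv <- info[!late & !short, ]
  n_by_exp <- table(surv$experiment_id)
  bad_exp <- names(n_by_exp)[n_by_exp < config$min_traces_per_experiment]
  if (length(bad_exp)) {
    drop <- surv$experiment_id %in% bad_exp
    report$exp <- data.frame(trace_id = surv$trace_id[drop],
                             experiment_id = surv$experiment_id[drop],
                             rule = "experiment_size")
    surv <- surv[!drop, ]
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(trace_id = character(0), experiment_id = character(0),
               rule = character(0))
  rownames(report) <- NULL
  list(traces = traces[traces$trace_id %in% surv$trace_id, ],
       report = report)
}

#' Segment a steady-state trace into translated and silent periods
#'
#' Burst calling on the smoothed trace with hysteresis: a translated
#' (active) period starts when the smoothed intensity rises above
#' `b0 + 3 * b0 * noise` and ends when it falls below `b0 + b0 * noise`;
#' runs shorter than `min_frames` are merged into their neighbours.
#'
#' @param y raw intensities.
#' @param times frame times, seconds.
#' @param noise multiplicative noise magnitude (CV).
#' @param b0 intensity offset, a.u.
#' @param config a [prep_config()].
#' @param min_frames minimum run length in frames.
#' @return A data.frame of intervals: `state` ("active"/"silent"),
#'   `t_start`, `t_end`, `duration`, `mean_intensity` (raw mean).
#' @export
segment_bursts <- function(y, times, noise, b0, config = prep_config(),
                           min_frames = 2L) {
  stopifnot(length(y) == length(times), b0 > 0, noise > 0)
  dt <- if (length(times) > 1) diff(times[1:2]) else 1
  sm <- lowpass_smooth(y, dt, config$lowpass_cutoff)
  enter <- b0 + 3 * b0 * noise
  exit <- b0 + 1 * b0 * noise
  state <- logical(length(y))
  active <- FALSE
  for (j in seq_along(sm)) {
    if (!active && sm[j] > enter) active <- TRUE
    if (active && sm[j] < exit) active <- FALSE
    state[j] <- active
  }
  ## enforce minimum run length
  r <- rle(state)
  while (length(r$lengths) > 1 && any(r$lengths < min_frames)) {
    i <- which(r$lengths < min_frames)[1]
    r$values[i] <- if (i == 1) r$values[i + 1] else r$values[i - 1]
    r <- rle(inverse.rle(r))
  }
  state <- inverse.rle(r)
  ## refine each transition to the half-amplitude crossing: the asymmetric
  ## enter/exit thresholds detect bursts robustly but bias the boundary
  ## placement.  The crossing is located on the median-prefiltered raw trace,
  ## whose edges are not blurred by the low-pass filter.
  r <- rle(state)
  if (length(r$lengths) > 1) {
    yref <- if (length(y) >= 3) stats::runmed(y, 3) else y
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    meds <- vapply(seq_along(starts), function(i)
      median(yref[starts[i]:ends[i]]), 0)
    for (i in seq_len(length(starts) - 1L)) {
      win <- starts[i]:ends[i + 1L]
      mid <- (meds[i] + meds[i + 1L]) / 2
      wj <- win[-length(win)]
      up <- yref[wj] <= mid & yref[wj + 1L] > mid
      down <- yref[wj] > mid & yref[wj + 1L] <= mid
      cross <- wj[if (r$values[i + 1L]) up else down]
      if (length(cross)) {
        b <- cross[which.min(abs(cross - ends[i]))] + 1L  # nearest crossing
        b <- min(max(b, starts[i] + 1L), ends[i + 1L])
        ## shift only the frames between the old boundary and the crossing
        if (b <= ends[i]) {
          state[b:ends[i]] <- r$values[i + 1L]
        } else if (b > ends[i] + 1L) {
          state[(ends[i] + 1L):(b - 1L)] <- r$values[i]
        }
      }
    }
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(
    state = ifelse(r$values, "active", "silent"),
    t_start = times[starts],
    t_end = times[ends],
    duration = times[ends] - times[starts],
    mean_intensity = vapply(seq_along(starts), function(i)
      mean(y[starts[i]:ends[i]]), 0)
  )
}

#' Empirical ribosome count and density from interval intensities
#'
#' Assuming ribosomes uniformly distributed along the transcript, the mean
#' intensity of a translated interval converts to a ribosome count as
#' `N = (mean - b0) / (gamma(0) * i_MP)` with `gamma(0) = 1 - L_S / (2L)`,
#' and to a density `rho = N * ell / L`.
#'
#' @param mean_intensity mean interval intensity (vectorized), a.u.
#' @param noise a [noise_model()].
#' @param geom a [reporter_geometry()].
#' @return A data.frame with `N_hat` and `rho_hat`.
#' @export
empirical_density <- function(mean_intensity, noise, geom) {
  stopifnot(inherits(noise, "noise_model"), inherits(geom, "reporter_geometry"))
  g0 <- gamma_t(0, 1, geom$L, geom$L_S)
  N_hat <- pmax(0, (mean_intensity - noise$b0) / (g0 * noise$i_MP))
  data.frame(N_hat = N_hat, rho_hat = N_hat * geom$ell / geom$L)
}
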