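## Run-off hidden Markov model: the number of translating ribosomes N_t is a
## latent pure-death chain (no initiation after drug addition), observed
## through a lognormal intensity emission whose mean and scale depend on the
## run-off time through the correction factors gamma(t) and nu(t).

#' Specification of the run-off HMM
#'
#' Bundles the discretization constants of the hidden chain with the reporter
#' geometry and the noise calibration.
#'
#' @param geom a [reporter_geometry()].
#' @param noise a [noise_model()].
#' @param N_max maximum hidden ribosome count.
#' @param k_max maximum termination events per frame.
#' @param dt frame interval, seconds.
#' @param ht_delay delay between drug addition and run-off start, seconds.
#' @return An object of class `hmm_spec`.
#' @export
hmm_spec <- function(geom = reporter_geometry(), noise = noise_model(),
                     N_max = 100L, k_max = 6L, dt = 20, ht_delay = 60) {
  stopifnot(inherits(geom, "reporter_geometry"),
            inherits(noise, "noise_model"),
            N_max >= 1, k_max >= 1, k_max <= N_max, dt > 0, ht_delay >= 0)
  structure(
    list(geom = geom, noise = noise, N_max = as.integer(N_max),
         k_max = as.integer(k_max), dt = dt, ht_delay = ht_delay),
    class = "hmm_spec"
  )
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(sprintf("run-off HMM: N_max = %d, k_max = %d, dt = %g s, HT delay = %g s\n",
              x$N_max, x$k_max, x$dt, x$ht_delay))
  print(x$geom)
  print(x$noise)
  invisible(x)
}

#' Initial hidden-state probabilities of a run-off trace
#'
#' At run-off start the ribosome count on an active transcript is Poisson
#' with mean `alpha * L / lam`; a trace observed from `t_r` seconds into the
#' run-off gets the reduced mean `alpha * (L / lam - t_r)`.  The probability
#' that the transcript is translationally silent is the free parameter
#' `p_off`; the Poisson law, zero-truncated and renormalized over
#' `1..N_max`, carries the remaining mass.
#'
#' @param alpha initiation rate, 1/s.
#' @param lam elongation rate, codons/s.
#' @param p_off probability of a silent transcript at run-off start.
#' @param t_r trace start offset since run-off start, seconds
#'   (`t_r < L / lam`).
#' @param spec an [hmm_spec()].
#' @return Probability vector over `N = 0..N_max` (sums to 1).
#' @export
initial_state_probs <- function(alpha, lam, p_off, t_r, spec) {
  stopifnot(alpha > 0, lam > 0, p_off >= 0, p_off <= 1)
  L <- spec$geom$L
  if (t_r >= L / lam)
    stop("trace starts at t_r >= L/lam: no ribosome could remain")
  m <- alpha * (L / lam - t_r)
  p <- dpois(seq_len(spec$N_max), m)
  c(p_off, (1 - p_off) * p / sum(p))
}

#' Run-off transition matrix
#'
#' Between consecutive frames the ribosome count can only decrease; the
#' number of terminations per frame is Poisson with mean `alpha * dt`
#' (the stationary termination rate equals the initiation rate), truncated at
#' `min(k_max, N)` and renormalized row-wise.  State 0 is absorbing.
#'
#' @inheritParams initial_state_probs
#' @return A `(N_max + 1) x (N_max + 1)` row-stochastic matrix; entry
#'   `[N + 1, N - k + 1]` is the probability of `k` terminations.
#' @export
transition_matrix <- function(alpha, spec) {
  stopifnot(alpha >= 0)
  S <- spec$N_max + 1L
  pk <- dpois(0:spec$k_max, alpha * spec$dt)
  G <- matrix(0, S, S)
  for (n in 0:spec$N_max) {
    kmx <- min(spec$k_max, n)
    p <- pk[1:(kmx + 1)]
    G[n + 1L, (n:(n - kmx)) + 1L] <- p / sum(p)
  }
  G
}

## gamma(t), s(t) and state-wise lognormal parameters on a time grid.
## Returns meanlog (T x S) and sdlog (T x S) matrices.
emission_pars <- function(times, alpha, lam, i_MP, spec) {
  geom <- spec$geom
  noise <- spec$noise
  g <- gamma_t(times, lam, geom$L, geom$L_S)
  s <- noise_scale_s(times, alpha, lam, geom$L, geom$L_S, noise$s0)
  n <- 0:spec$N_max
  mu <- noise$b0 + outer(g, n) * i_MP           # T x S
  sdlog <- matrix(s, length(times), spec$N_max + 1L)
  sdlog[, 1L] <- noise$s0                        # N = 0: measurement noise only
  list(meanlog = log(mu), sdlog = sdlog)
}

#' Lognormal emission log-density
#'
#' Probability density of observing intensity `y` given `N` translating
#' ribosomes `t` seconds into the run-off: lognormal with median
#' `b0 + gamma(t) * N * i_MP` and scale `s(t)` from [noise_scale_s()]
#' (the configurational term uses the ensemble mean `alpha * L / lam`, not
#' the hidden state); for `N = 0` the scale is the baseline `s0`.
#'
#' @param y observed intensity, a.u. (`> 0`).
#' @param N hidden ribosome count.
#' @param t run-off time of the frame, seconds.
#' @inheritParams initial_state_probs
#' @param i_MP mature-protein intensity; defaults to the value in `spec`.
#' @export
emission_logprob <- function(y, N, t, alpha, lam, spec, i_MP = NULL) {
  if (any(y <= 0))
    stop("intensities must be strictly positive (un-preprocessed trace?)")
  if (is.null(i_MP)) i_MP <- spec$noise$i_MP
  ep <- emission_pars(t, alpha, lam, i_MP, spec)
  dlnorm(y, ep$meanlog[cbind(seq_along(t), N + 1L)],
         ep$sdlog[cbind(seq_along(t), N + 1L)], log = TRUE)
}

split_traces <- function(traces) {
  stopifnot(all(c("trace_id", "time_s", "intensity") %in% names(traces)))
  if (is.null(traces$t_r)) traces$t_r <- 0
  lapply(split(traces, traces$trace_id), function(d) {
    d <- d[order(d$time_s), ]
    list(id = d$trace_id[1], y = d$intensity, times = d$time_s,
         t_r = d$t_r[1],
         censored = if (!is.null(d$censored)) any(d$censored) else FALSE,
         condition = if (!is.null(d$condition)) d$condition[1] else "all")
  })
}

## Scaled forward pass for one trace; emissions passed as a T x S log matrix.
forward_pass <- function(logE, theta, G, keep = FALSE) {
  Tn <- nrow(logE)
  S <- ncol(logE)
  ll <- 0
  f <- theta
  alphas <- if (keep) matrix(0, Tn, S) else NULL
  for (j in seq_len(Tn)) {
    le <- logE[j, ]
    c0 <- max(le)
    f <- f * exp(le - c0)
    tot <- sum(f)
    if (tot <= 0 || !is.finite(tot)) return(list(loglik = -Inf, alphas = alphas))
    ll <- ll + log(tot) + c0
    f <- f / tot
    if (keep) alphas[j, ] <- f
    if (j < Tn) f <- as.vector(f %*% G)
  }
  list(loglik = ll, alphas = alphas)
}

#' Forward-algorithm log-likelihood of one run-off trace
#'
#' Exact marginalization over all hidden ribosome-count paths, computed with
#' the scaled forward recursion.  Censored traces (tracking lost before the
#' run-off completes) contribute the likelihood of their observed frames
#' only.
#'
#' @param trace a single-trace data.frame (columns `time_s`, `intensity`,
#'   optionally `t_r`) with `time_s` on the `dt` grid, measured from run-off
#'   start.
#' @inheritParams emission_logprob
#' @param p_off probability of a silent transcript.
#' @export
forward_loglik <- function(trace, alpha, lam, p_off, spec, i_MP = NULL) {
  if (is.null(i_MP)) i_MP <- spec$noise$i_MP
  tr <- split_traces(trace)
  if (length(tr) != 1L) stop("forward_loglik() expects a single trace")
  tr <- tr[[1]]
  theta <- initial_state_probs(alpha, lam, p_off, tr$times[1], spec)
  G <- transition_matrix(alpha, spec)
  ep <- emission_pars(tr$times, alpha, lam, i_MP, spec)
  logE <- matrix(dlnorm(tr$y, ep$meanlog, ep$sdlog, log = TRUE),
                 length(tr$y), spec$N_max + 1L)
  forward_pass(logE, theta, G)$loglik
}

## Summed negative log-likelihood over a list of prepared traces.
nll_traces <- function(tr_list, alpha, lam, p_off, i_MP, spec) {
  G <- transition_matrix(alpha, spec)
  all_times <- sort(unique(unlist(lapply(tr_list, `[[`, "times"))))
  ep <- emission_pars(all_times, alpha, lam, i_MP, spec)
  ll <- 0
  for (tr in tr_list) {
    idx <- match(tr$times, all_times)
    logE <- matrix(dlnorm(tr$y, ep$meanlog[idx, , drop = FALSE],
                          ep$sdlog[idx, , drop = FALSE], log = TRUE),
                   length(tr$y), spec$N_max + 1L)
    theta <- initial_state_probs(alpha, lam, p_off, tr$times[1], spec)
    ll <- ll + forward_pass(logE, theta, G)$loglik
  }
  -ll
}

## Data-driven starting point: lambda from the median decay time of the
## smoothed ensemble signal, alpha from the mean initial intensity.
heuristic_start <- function(tr_list, spec) {
  noise <- spec$noise
  L <- spec$geom$L
  y0 <- vapply(tr_list, function(tr) tr$y[1], 0)
  g0 <- gamma_t(0, 1, L, spec$geom$L_S)
  N0 <- max(0.5, mean(pmax(y0 - noise$b0, 0)) / (g0 * noise$i_MP))
  ## time at which traces first fall to within noise of baseline
  t_done <- vapply(tr_list, function(tr) {
    thr <- noise$b0 * exp(2 * noise$s0)
    below <- which(tr$y < thr)
    if (length(below)) tr$times[below[1]] else max(tr$times)
  }, 0)
  lam0 <- min(9, max(0.2, L / max(stats::median(t_done), spec$dt)))
  alpha0 <- min(0.15, max(2e-4, N0 * lam0 / L))
  c(alpha = alpha0, lam = lam0)
}

fit_bounds <- list(alpha = c(1e-4, 0.2), lam = c(0.1, 10),
                   p_off = c(1e-4, 1 - 1e-4), i_MP = c(0.5, 200))

#' Fit the run-off HMM to a set of traces
#'
#' Maximizes the summed forward log-likelihood over traces with respect to
#' the initiation rate `alpha`, the elongation rate `lam`, the silent-state
#' probability `p_off`, and optionally the mature-protein intensity `i_MP`.
#' Optimization is bounded quasi-Newton (L-BFGS-B) on log / logit scales
#' (`alpha` in 1e-4..0.2 /s, `lam` in 0.1..10 codons/s), started from both a
#' default and a data-driven point; 95% intervals come from the observed
#' information (Laplace approximation) on the transformed scale.
#'
#' When the trace table carries more than one `condition`, each condition
#' gets its own `alpha`, `lam` and `p_off`, while `i_MP` (if free) is shared
#' across conditions.
#'
#' @param traces long-format trace data.frame (see
#'   [simulate_runoff_traces()] for the columns).
#' @param spec an [hmm_spec()].
#' @param free character vector of free parameters, a subset of
#'   `c("alpha", "lam", "p_off", "i_MP")`.
#' @param fixed named list overriding fixed parameter values (`i_MP` and
#'   `p_off` default to the `spec` value and 0.1).
#' @param start optional named list of starting values.
#' @param min_traces minimum number of traces per condition.
#' @return An object of class `runoff_fit` with per-condition estimates,
#'   intervals, the inferred density `rho = ell * alpha / lam`, the total
#'   log-likelihood and optimizer diagnostics.
#' @export
fit_runoff <- function(traces, spec, free = c("alpha", "lam", "p_off"),
                       fixed = list(), start = list(), min_traces = 10L) {
  stopifnot(inherits(spec, "hmm_spec"))
  free <- match.arg(free, c("alpha", "lam", "p_off", "i_MP"),
                    several.ok = TRUE)
  if (!all(c("alpha", "lam") %in% free))
    stop("alpha and lam must be free parameters")
  tr_all <- split_traces(traces)
  conds <- sort(unique(vapply(tr_all, `[[`, "", "condition")))
  by_cond <- lapply(conds, function(cn)
    tr_all[vapply(tr_all, `[[`, "", "condition") == cn])
  names(by_cond) <- conds
  n_per <- vapply(by_cond, length, 0L)
  if (any(n_per < min_traces))
    stop("conditions with fewer than ", min_traces, " traces: ",
         paste(conds[n_per < min_traces], collapse = ", "))

  defaults <- list(alpha = 1 / 60, lam = 3, p_off = 0.1,
                   i_MP = spec$noise$i_MP)
  fixed_vals <- utils::modifyList(defaults, fixed)

  ## transformed parameter vector: per condition (alpha, lam[, p_off]),
  ## then shared i_MP if free
  per_cond <- intersect(c("alpha", "lam", "p_off"), free)
  tx <- function(p, nm) if (nm == "p_off") qlogis(p) else log(p)
  itx <- function(z, nm) if (nm == "p_off") plogis(z) else exp(z)

  par_names <- c(as.vector(t(outer(conds, per_cond, paste, sep = "."))),
                 if ("i_MP" %in% free) "i_MP")
  unpack <- function(z) {
    out <- lapply(conds, function(cn) {
      p <- fixed_vals
      for (nm in per_cond)
        p[[nm]] <- itx(z[paste(cn, nm, sep = ".")], nm)
      if ("i_MP" %in% free) p$i_MP <- exp(z[["i_MP"]])
      p
    })
    names(out) <- conds
    out
  }
  obj <- function(z) {
    names(z) <- par_names
    ps <- unpack(z)
    tot <- 0
    for (cn in conds) {
      p <- ps[[cn]]
      tot <- tot + nll_traces(by_cond[[cn]], p$alpha, p$lam, p$p_off,
                              p$i_MP, spec)
    }
    if (!is.finite(tot)) tot <- 1e10
    tot
  }

  make_z <- function(vals_by_cond, i_MP_val) {
    z <- numeric(0)
    for (cn in conds)
      for (nm in per_cond)
        z[paste(cn, nm, sep = ".")] <- tx(vals_by_cond[[cn]][[nm]], nm)
    if ("i_MP" %in% free) z[["i_MP"]] <- log(i_MP_val)
    z
  }
  clamp <- function(v, b) pmin(pmax(v, b[1] * 1.01), b[2] * 0.99)
  start_default <- lapply(conds, function(cn) {
    p <- utils::modifyList(fixed_vals, start)
    p
  })
  names(start_default) <- conds
  start_heur <- lapply(conds, function(cn) {
    h <- heuristic_start(by_cond[[cn]], spec)
    p <- utils::modifyList(fixed_vals, start)
    p$alpha <- clamp(h[["alpha"]], fit_bounds$alpha)
    p$lam <- clamp(h[["lam"]], fit_bounds$lam)
    p
  })
  names(start_heur) <- conds
  starts <- list(default = start_default, heuristic = start_heur)

  lower <- upper <- numeric(length(par_names))
  names(lower) <- names(upper) <- par_names
  for (cn in conds)
    for (nm in per_cond) {
      lower[paste(cn, nm, sep = ".")] <- tx(fit_bounds[[nm]][1], nm)
      upper[paste(cn, nm, sep = ".")] <- tx(fit_bounds[[nm]][2], nm)
    }
  if ("i_MP" %in% free) {
    lower[["i_MP"]] <- log(fit_bounds$i_MP[1])
    upper[["i_MP"]] <- log(fit_bounds$i_MP[2])
  }

  best <- NULL
  for (st in starts) {
    z0 <- make_z(st, st[[1]]$i_MP)
    res <- tryCatch(
      optim(z0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300, factr = 1e8)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) stop("run-off fit failed from every starting point")
  if (best$convergence != 0)
    warning("optimizer did not report clean convergence (code ",
            best$convergence, "): ", best$message)

  ## observed information on the transformed scale
  z_hat <- best$par
  names(z_hat) <- par_names
  H <- tryCatch(optimHess(z_hat, obj), error = function(e) NULL)
  se_z <- rep(NA_real_, length(par_names))
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se_z <- sqrt(diag(V))
  }
  if (anyNA(se_z))
    warning("observed information is not positive definite; ",
            "some intervals are NA")
  names(se_z) <- par_names

  est_rows <- list()
  ps <- unpack(z_hat)
  for (cn in conds) {
    for (nm in per_cond) {
      key <- paste(cn, nm, sep = ".")
      zv <- z_hat[[key]]; se <- se_z[[key]]
      est_rows[[key]] <- data.frame(
        condition = cn, param = nm, estimate = itx(zv, nm),
        lower = if (is.na(se)) NA_real_ else itx(zv - 1.96 * se, nm),
        upper = if (is.na(se)) NA_real_ else itx(zv + 1.96 * se, nm))
    }
    est_rows[[paste0(cn, ".rho")]] <- data.frame(
      condition = cn, param = "rho",
      estimate = spec$geom$ell * ps[[cn]]$alpha / ps[[cn]]$lam,
      lower = NA_real_, upper = NA_real_)
  }
  if ("i_MP" %in% free) {
    zv <- z_hat[["i_MP"]]; se <- se_z[["i_MP"]]
    est_rows[["i_MP"]] <- data.frame(
      condition = "shared", param = "i_MP", estimate = exp(zv),
      lower = if (is.na(se)) NA_real_ else exp(zv - 1.96 * se),
      upper = if (is.na(se)) NA_real_ else exp(zv + 1.96 * se))
  }
  estimates <- do.call(rbind, est_rows)
  rownames(estimates) <- NULL

  structure(
    list(estimates = estimates, params = ps, free = free,
         fixed = fixed_vals[setdiff(names(fixed_vals), free)],
         loglik = -best$value, convergence = best$convergence,
         counts = best$counts, n_traces = n_per, spec = spec),
    class = "runoff_fit"
  )
}

#' @export
print.runoff_fit <- function(x, ...) {
  cat(sprintf("run-off HMM fit: %d trace(s), logLik = %.2f\n",
              sum(x$n_traces), x$loglik))
  df <- x$estimates
  df$estimate <- signif(df$estimate, 4)
  df$lower <- signif(df$lower, 4)
  df$upper <- signif(df$upper, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract fitted parameters for one condition
#'
#' @param fit a `runoff_fit`.
#' @param condition condition label; defaults to the first.
#' @return Named list with `alpha`, `lam`, `p_off`, `i_MP`.
#' @export
fit_params <- function(fit, condition = NULL) {
  stopifnot(inherits(fit, "runoff_fit"))
  if (is.null(condition)) condition <- names(fit$params)[1]
  fit$params[[condition]][c("alpha", "lam", "p_off", "i_MP")]
}

#' Decode the ribosome-count path of one run-off trace
#'
#' Forward-backward posterior over `N` per frame plus the max-product
#' (Viterbi) path.  The run-off time is the first frame at which the decoded
#' path reaches 0; if the path never reaches 0 the trace duration is
#' reported as a lower bound and the trace is flagged censored.
#'
#' @param trace single-trace data.frame (columns `time_s`, `intensity`).
#' @param alpha,lam,p_off,i_MP model parameters, e.g. from [fit_params()].
#' @param spec an [hmm_spec()].
#' @return An object of class `decoded_trace`: `times`, `posterior`
#'   (frames x states, rows sum to 1), `path`, `runoff_time`, `censored`.
#' @export
decode_trace <- function(trace, alpha, lam, p_off, spec, i_MP = NULL) {
  if (is.null(i_MP)) i_MP <- spec$noise$i_MP
  tr <- split_traces(trace)
  if (length(tr) != 1L) stop("decode_trace() expects a single trace")
  tr <- tr[[1]]
  S <- spec$N_max + 1L
  Tn <- length(tr$y)
  theta <- initial_state_probs(alpha, lam, p_off, tr$times[1], spec)
  G <- transition_matrix(alpha, spec)
  ep <- emission_pars(tr$times, alpha, lam, i_MP, spec)
  logE <- matrix(dlnorm(tr$y, ep$meanlog, ep$sdlog, log = TRUE), Tn, S)

  fw <- forward_pass(logE, theta, G, keep = TRUE)
  ## scaled backward pass
  beta <- matrix(0, Tn, S)
  beta[Tn, ] <- 1
  if (Tn > 1) {
    for (j in (Tn - 1):1) {
      le <- logE[j + 1, ]
      c0 <- max(le)
      b <- as.vector(G %*% (exp(le - c0) * beta[j + 1, ]))
      beta[j, ] <- b / sum(b)
    }
  }
  post <- fw$alphas * beta
  post <- post / rowSums(post)

  ## Viterbi (max-product) path in log space
  logG <- log(G)
  delta <- log(theta) + logE[1, ]
  back <- matrix(0L, Tn, S)
  if (Tn > 1) {
    for (j in 2:Tn) {
      cand <- delta + logG  # S x S: previous state x next state
      back[j, ] <- max.col(t(cand), ties.method = "last")
      delta <- cand[cbind(back[j, ], seq_len(S))] + logE[j, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta) - 1L
  if (Tn > 1)
    for (j in (Tn - 1):1) path[j] <- back[j + 1, path[j + 1] + 1L] - 1L

  hit <- which(path == 0L)
  censored <- length(hit) == 0L
  structure(
    list(id = tr$id, times = tr$times, posterior = post, path = path,
         runoff_time = if (censored) tr$times[Tn] else tr$times[hit[1]],
         censored = censored || tr$censored,
         loglik = fw$loglik),
    class = "decoded_trace"
  )
}

#' @export
print.decoded_trace <- function(x, ...) {
  cat(sprintf("decoded trace %s: %d frames, N %d -> %d, run-off time %s%g s\n",
              x$id, length(x$times), x$path[1], x$path[length(x$path)],
              if (x$censored) ">= " else "", x$runoff_time))
  invisible(x)
}

#' Decode every trace in a table
#'
#' @param traces long-format trace data.frame.
#' @param fit a `runoff_fit` (parameters are taken per condition), or `NULL`
#'   if explicit parameters are given.
#' @inheritParams decode_trace
#' @return A list of `decoded_trace` objects.
#' @export
decode <- function(traces, fit = NULL, spec = NULL, alpha = NULL, lam = NULL,
                   p_off = NULL, i_MP = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "runoff_fit"))
    spec <- fit$spec
  }
  stopifnot(inherits(spec, "hmm_spec"))
  ids <- unique(traces$trace_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    tr <- traces[traces$trace_id == id, ]
    if (!is.null(fit)) {
      cn <- if (!is.null(tr$condition)) tr$condition[1] else names(fit$params)[1]
      if (!cn %in% names(fit$params)) cn <- names(fit$params)[1]
      p <- fit$params[[cn]]
      out[[id]] <- decode_trace(tr, p$alpha, p$lam, p$p_off, spec, p$i_MP)
    } else {
      out[[id]] <- decode_trace(tr, alpha, lam, p_off, spec, i_MP)
    }
  }
  out
}

#' Termination event times of a decoded path
#'
#' Each decrement of the decoded path by `k` corresponds to `k` termination
#' events inside that frame interval.  Decoded event times are interval-
#' censored to the frame grid; with `impute = "uniform"` the events are
#' placed uniformly at random within their frame, the standard randomized
#' treatment when comparing against a continuous waiting-time law.
#'
#' @param decoded a `decoded_trace`.
#' @param impute `"none"` (events at the frame end) or `"uniform"`.
#' @return Sorted numeric vector of event times, seconds.
#' @export
termination_times <- function(decoded, impute = c("none", "uniform")) {
  impute <- match.arg(impute)
  stopifnot(inherits(decoded, "decoded_trace"))
  drops <- -diff(decoded$path)
  ev <- numeric(0)
  for (j in which(drops > 0)) {
    k <- drops[j]
    t0 <- decoded$times[j]
    t1 <- decoded$times[j + 1]
    ev <- c(ev, if (impute == "uniform") runif(k, t0, t1) else rep(t1, k))
  }
  sort(ev)
}

#' Summarize a set of decoded run-off traces
#'
#' Run-off time distribution, fraction of incomplete (censored) run-offs,
#' fraction of traces still translating at a reference time (15 min by
#' default, counted among traces whose status at that time is known), and
#' the waiting times between successive decoded termination events.
#'
#' @param decoded_list list of `decoded_trace` objects (from [decode()]).
#' @param still_at reference time for the still-translating fraction,
#'   seconds.
#' @param impute waiting-time imputation passed to [termination_times()].
#' @return A list with `per_trace` (data.frame), `frac_incomplete`,
#'   `frac_still_translating`, `waiting_times`.
#' @export
runoff_summary <- function(decoded_list, still_at = 900,
                           impute = c("none", "uniform")) {
  impute <- match.arg(impute)
  per <- do.call(rbind, lapply(decoded_list, function(d) {
    data.frame(trace_id = d$id, runoff_time = d$runoff_time,
               censored = d$censored, n0 = d$path[1],
               last_time = d$times[length(d$times)])
  }))
  rownames(per) <- NULL
  known <- !per$censored | per$last_time >= still_at
  still <- per$runoff_time > still_at |
    (per$censored & per$last_time >= still_at)
  wt <- unlist(lapply(decoded_list, function(d) {
    ev <- termination_times(d, impute)
    if (length(ev) > 1) diff(ev) else numeric(0)
  }))
  list(per_trace = per,
       frac_incomplete = mean(per$censored),
       frac_still_translating = if (any(known)) mean(still[known]) else NA_real_,
       waiting_times = as.numeric(wt))
}
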