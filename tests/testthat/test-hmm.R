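spec_small <- function(N_max = 3, k_max = 2, s0 = 0.3)
  hmm_spec(geom = small_geom(), noise = noise_model(s0 = s0),
           N_max = N_max, k_max = k_max, dt = 20)

spec_paper <- function(s0 = 0.3, i_MP = 14)
  hmm_spec(geom = paper_geom(), noise = noise_model(i_MP = i_MP, s0 = s0))

test_that("initial state law: silent mass, normalization, Poisson mode", {
  sp <- spec_paper()
  th <- initial_state_probs(1 / 60, 3, p_off = 1, t_r = 0, spec = sp)
  expect_equal(th, c(1, rep(0, sp$N_max)))
  for (p_off in c(0.05, 0.3)) {
    th <- initial_state_probs(1 / 60, 3, p_off, t_r = 40, spec = sp)
    expect_equal(sum(th), 1)
    expect_equal(th[1], p_off)
  }
  # mean alpha*L/lam = 5.92: Poisson mode at floor of the mean
  th <- initial_state_probs(1 / 60, 3, 0.1, 0, sp)
  expect_equal(which.max(th[-1]), 5)  # th[-1][N] is the mass of state N
  expect_error(initial_state_probs(1 / 60, 3, 0.1, t_r = 400, spec = sp),
               "t_r")
})

test_that("transition matrix: pure-death support, absorbing zero, stochastic rows", {
  sp <- spec_paper()
  G0 <- transition_matrix(0, sp)
  expect_equal(G0, diag(sp$N_max + 1))
  G <- transition_matrix(1 / 60, sp)
  expect_equal(rowSums(G), rep(1, sp$N_max + 1))
  expect_equal(G[1, 1], 1)  # state 0 absorbing
  # no upward moves, no drops beyond k_max
  expect_true(all(G[upper.tri(G)] == 0))
  for (n in seq(8, sp$N_max, by = 17))
    expect_true(all(G[n + 1, seq_len(n - sp$k_max)] == 0))
  # truncation discards little mass at the paper's fastest plausible rate
  expect_lt(1 - sum(dpois(0:6, 0.08 * 20)), 6e-3)
})

test_that("emission law: baseline and plateau regimes", {
  sp <- spec_paper(s0 = 0.31)
  # no ribosomes: lognormal around b0 with the baseline scale
  lp <- emission_logprob(6.0, 0, t = 100, alpha = 1 / 60, lam = 3, spec = sp)
  expect_equal(lp, dlnorm(6, log(6), 0.31, log = TRUE))
  # all ribosomes past the SunTag (lam*t >= L_S): median b0 + N*i_MP, scale s0
  t_late <- sp$geom$L_S / 3 + 20
  lp <- emission_logprob(6 + 4 * 14, 4, t_late, 1 / 60, 3, sp)
  expect_equal(lp, dlnorm(6 + 56, log(6 + 56), 0.31, log = TRUE))
  expect_error(emission_logprob(-1, 0, 0, 1 / 60, 3, sp), "positive")
})

test_that("replicated noisy draws peak the emission density at the truth", {
  sp <- spec_paper(s0 = 0.2)
  set.seed(33)
  t0 <- 40; N_true <- 5
  g <- gamma_t(t0, 3, sp$geom$L, sp$geom$L_S)
  mu <- 6 + g * N_true * 14
  y <- add_lognormal_noise(rep(mu, 400), noise_scale_s(t0, 1 / 60, 3,
                                                       sp$geom$L, sp$geom$L_S, 0.2))
  tot <- vapply(0:12, function(n)
    sum(emission_logprob(y, rep(n, length(y)), rep(t0, length(y)),
                         1 / 60, 3, sp)), 0)
  expect_equal(which.max(tot) - 1, N_true)
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
  sp <- spec_small(N_max = 3, k_max = 2)
  set.seed(2024)
  cases <- list(
    list(alpha = 1 / 60, lam = 3, p_off = 0.1, i_MP = 14,
         y = c(40, 30, 22, 8), times = c(0, 20, 40, 60)),
    list(alpha = 1 / 100, lam = 1.5, p_off = 0.4, i_MP = 10,
         y = c(7, 20, 12, 6, 6), times = c(20, 40, 60, 80, 100)),
    list(alpha = 0.03, lam = 5, p_off = 0.01, i_MP = 20,
         y = c(55, 41, 18), times = c(0, 20, 40))
  )
  for (cs in cases) {
    tr <- data.frame(trace_id = "t1", time_s = cs$times, intensity = cs$y)
    ll_fwd <- forward_loglik(tr, cs$alpha, cs$lam, cs$p_off, sp,
                             i_MP = cs$i_MP)
    ll_enum <- enumerate_loglik(cs$y, cs$times, cs$alpha, cs$lam, cs$p_off,
                                cs$i_MP, sp)
    expect_equal(ll_fwd, ll_enum, tolerance = 1e-11)
  }
  # single-frame base case: log of the initial-times-emission dot product
  tr1 <- data.frame(trace_id = "t1", time_s = 0, intensity = 30)
  th <- initial_state_probs(1 / 60, 3, 0.1, 0, sp)
  em <- exp(emission_logprob(rep(30, 4), 0:3, rep(0, 4), 1 / 60, 3, sp,
                             i_MP = 14))
  expect_equal(forward_loglik(tr1, 1 / 60, 3, 0.1, sp, i_MP = 14),
               log(sum(th * em)), tolerance = 1e-12)
})

test_that("decoding a near-noiseless trace recovers the true ribosome path", {
  g <- paper_geom()
  p <- low_density_params()
  nm <- noise_model(b0 = 6, i_MP = 14, s0 = 0.01)
  sp <- hmm_spec(geom = g, noise = nm, N_max = 30)
  df <- simulate_runoff_traces(6, g, p, nm, dt = 20, seed = 44,
                               window = FALSE)
  # At early frames a just-initiated ribosome carries almost no epitopes, so
  # N vs N-1 is not identifiable even without measurement noise; exact
  # recovery is required once every ribosome has cleared the SunTag
  # (gamma = 1, nu = 0), near-exact before.
  t_clear <- g$L_S / p$lam
  for (id in unique(df$trace_id)) {
    tr <- df[df$trace_id == id, ]
    dec <- decode_trace(tr, p$alpha, p$lam, 0.05, sp)
    late <- tr$time_s >= t_clear
    expect_identical(dec$path[late], as.integer(tr$n_true[late]))
    expect_gt(mean(dec$path == tr$n_true), 0.85)
    expect_equal(rowSums(dec$posterior), rep(1, nrow(dec$posterior)))
    expect_true(all(diff(dec$path) <= 0))
    expect_false(dec$censored)
    expect_equal(dec$runoff_time, tr$time_s[which(tr$n_true == 0)[1]])
  }
})

test_that("a trace cut before completion is decoded as censored", {
  g <- paper_geom()
  p <- low_density_params()
  nm <- noise_model(s0 = 0.01)
  sp <- hmm_spec(geom = g, noise = nm, N_max = 30)
  df <- simulate_runoff_traces(4, g, p, nm, dt = 20, seed = 91,
                               window = FALSE)
  df1 <- do.call(rbind, lapply(split(df, df$trace_id), function(d)
    d[d$n_true > 0, ]))  # drop the completed tail
  df1 <- df1[df1$trace_id == df1$trace_id[1], ]
  dec <- decode_trace(df1, p$alpha, p$lam, 0.05, sp)
  expect_true(dec$censored)
  expect_equal(dec$runoff_time, max(df1$time_s))
})

test_that("run-off summaries: completeness, still-translating, stall contrast", {
  mk_decoded <- function(id, gaps, dt = 20) {
    ev <- cumsum(gaps)
    tmax <- max(ev) + dt
    times <- seq(0, ceiling(tmax / dt) * dt, by = dt)
    path <- vapply(times, function(t) sum(ev > t), 0L)
    structure(list(id = id, times = times, path = path,
                   runoff_time = times[which(path == 0L)[1]],
                   censored = FALSE, posterior = NULL, loglik = NA),
              class = "decoded_trace")
  }
  set.seed(8)
  # homogeneous gaps: all complete, none translating at 15 min
  dl <- lapply(1:20, function(i) mk_decoded(i, rexp(4, 1 / 60)))
  sm <- runoff_summary(dl, still_at = 900)
  expect_equal(sm$frac_incomplete, 0)
  expect_equal(sm$frac_still_translating, 0)
  expect_true(all(sm$waiting_times >= 0))
  # injected 400-s stalls: KS strongly rejects the low-density waiting law
  dl_stall <- lapply(1:30, function(i) mk_decoded(i, rep(400, 5)))
  sm_stall <- runoff_summary(dl_stall, impute = "uniform")
  ks <- suppressWarnings(ks.test(sm_stall$waiting_times, function(q)
    termination_waiting_cdf(q, 1 / 60, 3)))
  expect_lt(ks$p.value, 0.05)
})

test_that("fit_runoff recovers rates on a clean synthetic ensemble", {
  g <- paper_geom()
  p <- low_density_params()
  nm <- noise_model(b0 = 6, i_MP = 14, s0 = 0.2)
  sp <- hmm_spec(geom = g, noise = nm, N_max = 40)
  df <- simulate_runoff_traces(40, g, p, nm, dt = 20, seed = 7)
  fit <- fit_runoff(df, sp, free = c("alpha", "lam", "p_off"))
  est <- fit$params[[1]]
  expect_lt(abs(est$alpha - p$alpha) / p$alpha, 0.25)
  expect_lt(abs(est$lam - p$lam) / p$lam, 0.25)
  # interval sanity: point estimates inside their own 95% intervals
  e <- fit$estimates
  ok <- !is.na(e$lower)
  expect_true(all(e$estimate[ok] >= e$lower[ok] &
                    e$estimate[ok] <= e$upper[ok]))
  expect_error(fit_runoff(df[df$trace_id %in% unique(df$trace_id)[1:5], ],
                          sp), "fewer than")
})
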