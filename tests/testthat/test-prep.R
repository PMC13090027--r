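make_arrested <- function(n_traces, s0, slope, I0 = 30, n_frames = 40,
                          dt = 20) {
  do.call(rbind, lapply(seq_len(n_traces), function(r) {
    tt <- seq(0, by = dt, length.out = n_frames)
    mu <- pmax(I0 + slope * tt, 1)
    data.frame(trace_id = sprintf("chx_%03d", r), time_s = tt,
               intensity = add_lognormal_noise(mu, s0))
  }))
}

test_that("multiplicative noise recovery is accurate and bleach-invariant", {
  set.seed(61)
  est <- estimate_multiplicative_noise(make_arrested(80, s0 = 0.36,
                                                     slope = -0.01))
  expect_equal(est$s0, 0.36, tolerance = 0.02)
  # independent of the injected bleach slope
  s0_by_slope <- vapply(c(0, -0.005, -0.02), function(sl) {
    set.seed(62)
    estimate_multiplicative_noise(make_arrested(60, 0.36, sl))$s0
  }, 0)
  expect_lt(max(s0_by_slope) - min(s0_by_slope), 0.02)
  # noiseless constant traces have zero CV
  flat <- make_arrested(5, s0 = 0, slope = 0)
  expect_equal(estimate_multiplicative_noise(flat)$noise, 0)
})

test_that("despiking replaces only flagged frames and is idempotent", {
  set.seed(63)
  y <- rep(20, 40)
  y[15] <- 44   # > 2x the smoothed level
  y[30] <- 22   # 10% blip, below 2 * noise = 70%
  d <- despike(y, dt = 20, noise = 0.35)
  expect_true(d$replaced[15])
  expect_false(d$replaced[30])
  expect_lt(d$y[15], 30)
  untouched <- !d$replaced
  expect_identical(d$y[untouched], y[untouched])
  # idempotence on a noisy fixture
  y2 <- add_lognormal_noise(rep(25, 50), 0.2)
  y2[c(10, 35)] <- y2[c(10, 35)] * 3
  once <- despike(y2, 20, 0.35)$y
  twice <- despike(once, 20, 0.35)$y
  expect_equal(twice, once, tolerance = 1e-8)
})

test_that("run-off filtering applies start, length and experiment-size rules", {
  mk <- function(id, t_r, span, exp = "e1") {
    tt <- seq(0, span, by = 20)
    data.frame(trace_id = id, experiment_id = exp, t_r = t_r, time_s = tt,
               intensity = 10)
  }
  # trace starting 120 s after HT (t_r = 60) is excluded by the start rule
  one <- filter_runoff_traces(rbind(mk("a", 60, 600), mk("b", 0, 600)),
                              prep_config(min_traces_per_experiment = 1))
  expect_false("a" %in% one$traces$trace_id)
  expect_true("b" %in% one$traces$trace_id)
  expect_equal(one$report$rule[one$report$trace_id == "a"], "start_after_HT")

  # 12 traces: 3 violate start, 1 violates length, 8 survivors < 10 minimum
  # -> the whole experiment is excluded, with both stages in the report
  traces <- do.call(rbind, c(
    lapply(1:3, function(i) mk(sprintf("late%d", i), t_r = 50, span = 600)),
    list(mk("short1", t_r = 0, span = 200)),
    lapply(1:8, function(i) mk(sprintf("ok%d", i), t_r = 10, span = 600))))
  res <- filter_runoff_traces(traces, prep_config())
  expect_equal(nrow(res$traces), 0)
  expect_setequal(unique(res$report$rule),
                  c("start_after_HT", "track_length", "experiment_size"))
  expect_equal(sum(res$report$rule == "experiment_size"), 8)
})

test_that("burst segmentation recovers square-wave active/silent periods", {
  b0 <- 6; i_MP <- 14; noise <- 0.2; dt <- 20
  # constant baseline: a single silent interval
  flat <- segment_bursts(rep(b0, 40), seq(0, by = dt, length.out = 40),
                         noise, b0)
  expect_equal(nrow(flat), 1)
  expect_equal(flat$state, "silent")
  # 10 min on / 5 min off square wave
  on_f <- 30; off_f <- 15
  y <- rep(c(rep(b0 + 5 * i_MP, on_f), rep(b0, off_f)), 4)
  tt <- seq(0, by = dt, length.out = length(y))
  seg <- segment_bursts(y, tt, noise, b0)
  act <- seg[seg$state == "active", ]
  sil <- seg[seg$state == "silent", ]
  inner_act <- act$duration[act$t_start > 0 & act$t_end < max(tt)]
  inner_sil <- sil$duration[sil$t_start > 0 & sil$t_end < max(tt)]
  expect_true(all(abs(inner_act - on_f * dt) <= 2 * dt))
  expect_true(all(abs(inner_sil - off_f * dt) <= 2 * dt))
  # mean active-interval intensity reflects the plateau
  expect_equal(mean(act$mean_intensity), b0 + 5 * i_MP, tolerance = 0.1)
})

test_that("telegraph traces: mean active duration grows with 1/k_off", {
  g <- small_geom()
  nm <- noise_model(s0 = 0.1)
  mean_active <- vapply(c(1 / 100, 1 / 400), function(k_off) {
    p <- kinetic_params(0.05, 3, k_on = 1 / 200, k_off = k_off)
    set.seed(71)
    tr <- simulate_bursting(g, p, duration = 60000, dt = 20)
    y <- add_lognormal_noise(epitope_signal(tr, g, nm), nm$s0)
    seg <- segment_bursts(y, tr$times, 0.15, nm$b0)
    mean(seg$duration[seg$state == "active"])
  }, 0)
  expect_gt(mean_active[2], mean_active[1])
})

test_that("empirical density inverts the intensity-to-count map", {
  g <- paper_geom()
  nm <- noise_model(b0 = 6, i_MP = 14)
  g0 <- 1 - g$L_S / (2 * g$L)
  expect_equal(empirical_density(6, nm, g)$N_hat, 0)
  ed <- empirical_density(6 + g0 * 8 * 14, nm, g)
  expect_equal(ed$N_hat, 8, tolerance = 1e-10)
  expect_equal(ed$rho_hat, 8 * g$ell / g$L, tolerance = 1e-10)
})

test_that("steady-state density estimate matches ell*alpha/lambda end-to-end", {
  g <- paper_geom()
  p <- low_density_params()
  nm <- noise_model(b0 = 6, i_MP = 14, s0 = 0.3)
  set.seed(73)
  ens <- simulate_steady_ensemble(g, p, 30, duration = 3000, dt = 20)
  mean_I <- mean(vapply(ens, function(tr)
    mean(add_lognormal_noise(epitope_signal(tr, g, nm), nm$s0)), 0))
  rho_hat <- empirical_density(mean_I, nm, g)$rho_hat
  # lognormal noise inflates the mean by exp(s0^2/2); tolerance covers it
  expect_equal(rho_hat, low_density_rho(p$alpha, p$lam, g$ell),
               tolerance = 0.15)
})
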