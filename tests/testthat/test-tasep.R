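test_that("argument validation rejects impossible lattices and grids", {
  g <- small_geom()
  p <- low_density_params()
  expect_error(reporter_geometry(L = 10, L_S = 5, ell = 10), "L <= ell")
  expect_error(simulate_steady_state(g, p, duration = 100, dt = 0), "dt")
  expect_error(simulate_steady_state(g, p, duration = 0), "duration")
  expect_error(simulate_bursting(g, p, duration = 100), "k_on")
  expect_error(kinetic_params(1 / 60, 3, k_on = 0.01), "both")
})

test_that("alpha = 0 leaves the lattice empty", {
  g <- small_geom()
  p <- kinetic_params(alpha = 0, lam = 3)
  set.seed(11)
  tr <- simulate_steady_state(g, p, duration = 600, dt = 20)
  expect_true(all(tr$n_ribosomes == 0))
  expect_true(all(tr$n_epitopes == 0))
  ro <- simulate_runoff(g, p, duration = 600, dt = 20)
  expect_true(all(ro$n_ribosomes == 0))
})

test_that("identical seeds reproduce identical traces", {
  g <- small_geom()
  p <- low_density_params()
  set.seed(42)
  a <- simulate_runoff(g, p, dt = 20)
  set.seed(42)
  b <- simulate_runoff(g, p, dt = 20)
  expect_identical(a$n_ribosomes, b$n_ribosomes)
  expect_identical(a$n_epitopes, b$n_epitopes)
})

test_that("every recorded frame satisfies the ell-exclusion constraint", {
  g <- small_geom()
  set.seed(7)
  for (p in list(low_density_params(),
                 kinetic_params(0.05, 3),  # high density
                 kinetic_params(1 / 60, 3, k_on = 0.01, k_off = 0.01))) {
    sim_fun <- if (p$telegraph) simulate_bursting else simulate_steady_state
    tr <- sim_fun(g, p, duration = 2000, dt = 20, keep_occupancy = TRUE)
    expect_true(check_exclusion(tr))
    ro <- simulate_runoff(g, p, duration = 2000, dt = 20,
                          keep_occupancy = TRUE)
    expect_true(check_exclusion(ro))
  }
})

test_that("event bookkeeping balances: N on the lattice = initiations - terminations", {
  g <- small_geom()
  p <- low_density_params()
  set.seed(5)
  tr <- simulate_steady_state(g, p, duration = 4000, dt = 20)
  n_final <- tr$n_ribosomes[length(tr$n_ribosomes)]
  expect_equal(n_final,
               tr$counts[["initiations"]] - tr$counts[["terminations"]])
  ro <- simulate_runoff(g, p, duration = 4000, dt = 20)
  expect_equal(0L, ro$counts[["initiations"]] - ro$counts[["terminations"]] -
                 ro$n_ribosomes[length(ro$n_ribosomes)])
})

test_that("steady-state occupancy and current match the mean-field law", {
  g <- small_geom()
  p <- low_density_params()  # rho ~ 0.056
  set.seed(21)
  dur <- 40000
  tr <- simulate_steady_state(g, p, duration = dur, dt = 20)
  J <- mean_field_current(p$alpha, p$lam, g$ell)
  # terminations form a near-renewal stream: Poisson-scale Monte-Carlo error
  n_term_rec <- tr$counts[["terminations"]]
  expect_lt(abs(n_term_rec - J * dur), 3 * sqrt(J * dur) + 20)
  # time-averaged density vs J * ell / lam
  rho_hat <- mean(tr$n_ribosomes) * g$ell / g$L
  expect_equal(rho_hat, J * g$ell / p$lam, tolerance = 0.1)
})

test_that("run-off traces are non-increasing and finish near L/lambda", {
  g <- paper_geom()
  p <- low_density_params()
  set.seed(31)
  ens <- simulate_runoff_ensemble(g, p, 400, dt = 20)
  mono <- vapply(ens, function(x) all(diff(x$n_ribosomes) <= 0), TRUE)
  expect_true(all(mono))
  ends <- vapply(ens, function(x) max(x$times), 0)
  travel <- g$L / p$lam  # 355 s
  # last ribosome: start position ~ 0 plus Gamma(L, lam) travel spread
  expect_lt(max(ends), travel + 5 * sqrt(g$L) / p$lam + 2 * 20)
  expect_gt(max(ends), travel - 60)  # some trace does take the full run
  zero_end <- vapply(ens, function(x) x$n_ribosomes[length(x$n_ribosomes)],
                     0L)
  expect_true(all(zero_end == 0L))
})

test_that("initial run-off ribosome counts are Poisson-like at low density", {
  g <- paper_geom()
  p <- kinetic_params(alpha = 1 / 120, lam = 5)  # rho ~ 0.017
  set.seed(13)
  ens <- simulate_runoff_ensemble(g, p, 1500, dt = 20)
  n0 <- vapply(ens, function(x) x$n_ribosomes[1], 0L)
  m_exp <- p$alpha * g$L / p$lam
  expect_lt(abs(mean(n0) - m_exp), 3 * sd(n0) / sqrt(length(n0)))
  disp <- var(n0) / mean(n0)
  expect_lt(abs(disp - 1), 3 * sqrt(2 / (length(n0) - 1)))
})

test_that("telegraph gene state follows the two-state stationary law", {
  g <- small_geom()
  p <- kinetic_params(1 / 60, 3, k_on = 1 / 200, k_off = 1 / 100)
  set.seed(17)
  tr <- simulate_bursting(g, p, duration = 80000, dt = 20)
  frac_on <- mean(tr$gene_state)
  expect_equal(frac_on, p$k_on / (p$k_on + p$k_off), tolerance = 0.12)
  expect_gt(tr$counts[["toggles"]], 100)
})

test_that("slow switching: active periods carry the steady-state occupancy", {
  g <- small_geom()
  p <- kinetic_params(1 / 60, 3, k_on = 1 / 2000, k_off = 1 / 2000)
  set.seed(19)
  tr <- simulate_bursting(g, p, duration = 120000, dt = 20)
  on <- tr$gene_state == 1
  expect_gt(sum(on), 100)
  m_exp <- p$alpha * g$L / p$lam
  expect_equal(mean(tr$n_ribosomes[on]), m_exp, tolerance = 0.2)
  # k_off -> 0: the active state is absorbing and bursting reduces to the
  # plain steady state
  p0 <- kinetic_params(1 / 60, 3, k_on = 1, k_off = 1e-9)
  set.seed(23)
  tr0 <- simulate_bursting(g, p0, duration = 20000, dt = 20)
  expect_true(all(tr0$gene_state == 1))
  expect_equal(mean(tr0$n_ribosomes), m_exp, tolerance = 0.25)
})
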