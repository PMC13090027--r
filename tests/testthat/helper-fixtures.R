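# Shared fixtures: small reporters and kinetic regimes used across tests.

small_geom <- function(weights = "integer")
  reporter_geometry(L = 300L, L_S = 100L, n_S = 24L, ell = 10L,
                    weights = weights)

paper_geom <- function(weights = "integer")
  reporter_geometry(L = 1066L, L_S = 528L, n_S = 24L, ell = 10L,
                    weights = weights)

low_density_params <- function() kinetic_params(alpha = 1 / 60, lam = 3)

# brute-force HMM likelihood by exhaustive path enumeration; the oracle is
# deliberately independent of the forward implementation
enumerate_loglik <- function(y, times, alpha, lam, p_off, i_MP, spec) {
  S <- spec$N_max + 1L
  theta <- initial_state_probs(alpha, lam, p_off, times[1], spec)
  G <- transition_matrix(alpha, spec)
  Tn <- length(y)
  paths <- as.matrix(expand.grid(rep(list(0:spec$N_max), Tn)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    pr <- theta[pth[1] + 1]
    if (Tn > 1)
      for (j in 2:Tn) pr <- pr * G[pth[j - 1] + 1, pth[j] + 1]
    if (pr == 0) next
    em <- exp(sum(emission_logprob(y, pth, times, alpha, lam, spec, i_MP)))
    tot <- tot + pr * em
  }
  log(tot)
}
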