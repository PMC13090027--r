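## Closed-form low-density l-TASEP quantities: current, density, run-off
## correction factors gamma(t) and nu(t), the termination waiting-time law
## and the time-dependent lognormal emission scale s(t).

#' Mean-field ribosome current in the initiation-limited regime
#'
#' `J = alpha * (lam - alpha) / (lam + (ell - 1) * alpha)`, the protein
#' synthesis rate per transcript in the continuum mean-field approximation of
#' the l-TASEP, valid in the initiation-limited phase.
#'
#' @param alpha initiation rate, 1/s.
#' @param lam elongation rate, codons/s (`lam > alpha`).
#' @param ell ribosome footprint, codons.
#' @return Current `J` in ribosomes per second.
#' @export
mean_field_current <- function(alpha, lam, ell) {
  stopifnot(all(alpha >= 0), all(lam > alpha))
  alpha * (lam - alpha) / (lam + (ell - 1) * alpha)
}

#' Low-density ribosome density
#'
#' `rho ~= (alpha / lam) * ell`, the fraction of the transcript covered by
#' ribosome footprints when elongation is much faster than initiation
#' (`lam / alpha >> ell`).  Warns when the approximation degrades.
#'
#' @inheritParams mean_field_current
#' @export
low_density_rho <- function(alpha, lam, ell) {
  stopifnot(all(alpha >= 0), all(lam > 0))
  if (any(alpha > 0 & lam / alpha <= 10 * ell))
    warning("lambda/alpha is not large compared to ell; ",
            "the low-density approximation is degrading")
  alpha / lam * ell
}

#' Ribosome density from a mean ribosome count
#'
#' `rho = N * ell / L`: the definition of density in terms of the average
#' number of ribosomes on the transcript.
#'
#' @param N average number of ribosomes.
#' @param ell ribosome footprint, codons.
#' @param L transcript length, codons.
#' @export
density_from_count <- function(N, ell, L) {
  stopifnot(all(N >= 0), ell >= 1, L > 0)
  N * ell / L
}

#' Run-off intensity correction factor gamma(t)
#'
#' Mean fractional brightness of a translating ribosome relative to one
#' mature protein, `t` seconds into a run-off, assuming ribosomes uniformly
#' distributed downstream of the run-off front at position `lam * t`:
#' `gamma(t) = 1 - (L_S - lam*t)^2 / (2 * L_S * (L - lam*t))` for
#' `lam*t <= L_S`, and 1 afterwards.  At t = 0 this reduces to
#' `1 - L_S / (2 L)`.
#'
#' With `discrete = TRUE` the exact finite-sum form over integer positions
#' `x_t = floor(lam*t)` is returned instead; the two agree to O(1/L_S).
#'
#' @param t time since run-off start, seconds (vectorized).
#' @param lam elongation rate, codons/s.
#' @param L,L_S transcript and SunTag lengths, codons.
#' @param discrete use the exact discrete-position sum.
#' @export
gamma_t <- function(t, lam, L, L_S, discrete = FALSE) {
  stopifnot(lam > 0, L_S > 0, L_S < L)
  lt <- lam * t
  if (discrete) {
    x_t <- floor(lt)
    g <- (L - L_S / 2 - x_t * (x_t - 1) / (2 * (L_S - 1))) / (L - x_t)
  } else {
    g <- 1 - (L_S - lt)^2 / (2 * L_S * (L - lt))
  }
  ifelse(lt >= L_S, 1, g)
}

#' Run-off per-ribosome intensity variance factor nu(t)
#'
#' Normalized variance of the brightness of one ribosome over its (uniform)
#' position distribution `t` seconds into a run-off; vanishes for
#' `lam*t >= L_S` once every ribosome has cleared the SunTag.  The variance
#' of the total intensity of N ribosomes is `nu(t) * N * i_MP^2`.
#'
#' @inheritParams gamma_t
#' @export
nu_t <- function(t, lam, L, L_S, discrete = FALSE) {
  stopifnot(lam > 0, L_S > 0, L_S < L)
  lt <- lam * t
  if (discrete) {
    x_t <- floor(lt)
    m2 <- (L_S * (2 * L_S - 1) / (6 * (L_S - 1)) + L - L_S -
             x_t * (2 * x_t - 1) * (x_t - 1) / (6 * (L_S - 1)^2)) / (L - x_t)
    nu <- m2 - gamma_t(t, lam, L, L_S, discrete = TRUE)^2
  } else {
    m2 <- (L - 2 * L_S / 3 - lt^3 / (3 * L_S^2)) / (L - lt)
    nu <- m2 - (1 - (L_S - lt)^2 / (2 * L_S * (L - lt)))^2
  }
  ifelse(lt >= L_S, 0, pmax(nu, 0))
}

#' Waiting-time density between successive termination events
#'
#' In the low-density regime the waiting time between terminations follows
#' `P(t) = alpha * (lam - alpha) / (lam - 2*alpha) * (exp(-alpha*t) -
#' exp(-(lam - alpha)*t))`, which for `alpha << lam` is close to the
#' exponential inter-initiation law `alpha * exp(-alpha * t)`.
#'
#' @param t waiting time, seconds (vectorized).
#' @param alpha initiation rate, 1/s.
#' @param lam elongation rate, codons/s; requires `lam > 2 * alpha`.
#' @export
termination_waiting_pdf <- function(t, alpha, lam) {
  stopifnot(alpha > 0, lam > 2 * alpha)
  alpha * (lam - alpha) / (lam - 2 * alpha) *
    (exp(-alpha * t) - exp(-(lam - alpha) * t))
}

#' Cumulative distribution of the termination waiting time
#'
#' Closed-form integral of [termination_waiting_pdf()].
#'
#' @inheritParams termination_waiting_pdf
#' @export
termination_waiting_cdf <- function(t, alpha, lam) {
  stopifnot(alpha > 0, lam > 2 * alpha)
  k <- alpha * (lam - alpha) / (lam - 2 * alpha)
  k * ((1 - exp(-alpha * t)) / alpha -
         (1 - exp(-(lam - alpha) * t)) / (lam - alpha))
}

#' Time-dependent lognormal emission noise scale s(t)
#'
#' Combines the baseline measurement noise `s0` with the configurational
#' uncertainty of the ribosome positions:
#' `s(t) = sqrt(log(1 + (exp(s0^2) - 1) + (lam / (alpha * L)) * nu(t) /
#' gamma(t)^2))`, where the mean ribosome count `alpha * L / lam` stands in
#' for the hidden state.  Once every ribosome has cleared the SunTag
#' (`nu(t) = 0`), `s(t) = s0` exactly.
#'
#' @inheritParams gamma_t
#' @param alpha initiation rate, 1/s.
#' @param s0 baseline lognormal noise scale.
#' @export
noise_scale_s <- function(t, alpha, lam, L, L_S, s0) {
  stopifnot(s0 > 0)
  nu <- nu_t(t, lam, L, L_S)
  if (any(nu > 0) && alpha <= 0)
    stop("alpha must be positive while nu(t) > 0")
  meas <- expm1(s0^2)
  conf <- if (alpha > 0) lam / (alpha * L) * nu else 0 * nu
  sqrt(log1p(meas + conf))
}

#' Tabulate the run-off correction factors on a time grid
#'
#' Convenience table of `gamma(t)`, `nu(t)` and `s(t)` for plotting or
#' export.
#'
#' @inheritParams noise_scale_s
#' @param t time grid, seconds.
#' @return A data.frame with columns `t`, `gamma`, `nu`, `s`.
#' @export
correction_table <- function(t, alpha, lam, L, L_S, s0) {
  data.frame(
    t = t,
    gamma = gamma_t(t, lam, L, L_S),
    nu = nu_t(t, lam, L, L_S),
    s = noise_scale_s(t, alpha, lam, L, L_S, s0)
  )
}
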