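#' Reporter geometry for a SunTag translation reporter
#'
#' Describes the transcript used in single-mRNA translation imaging: total
#' length, length of the N-terminal SunTag epitope array, number of epitopes,
#' ribosome footprint, and the cumulative-epitope weight vector `w` that maps
#' a ribosome position to the number of epitopes already synthesized (a linear
#' ramp over the SunTag followed by a plateau at `n_S`).
#'
#' With 1-based codon positions `x`, the epitope count is
#' `n(x) = n_S * (x - 1) / (L_S - 1)` for `x <= L_S` and `n_S` beyond.  By
#' default `w` is rounded to integer epitope counts; `weights = "continuous"`
#' keeps the exact linear ramp, which is what the closed-form correction
#' factors assume.
#'
#' @param L transcript length in codons.
#' @param L_S SunTag length in codons (`0 < L_S < L`).
#' @param n_S total number of epitopes in the array.
#' @param ell ribosome footprint in codons.
#' @param weights `"integer"` (rounded epitope counts) or `"continuous"`.
#' @return An object of class `reporter_geometry` with fields `L`, `L_S`,
#'   `n_S`, `ell` and the length-`L` weight vector `w`.
#' @examples
#' geom <- reporter_geometry(L = 1066, L_S = 528)
#' geom$w[geom$L_S]  # full epitope count once the SunTag is cleared
#' @export
reporter_geometry <- function(L = 1066L, L_S = 528L, n_S = 24L, ell = 10L,
                              weights = c("integer", "continuous")) {
  weights <- match.arg(weights)
  L <- as.integer(L); L_S <- as.integer(L_S)
  n_S <- as.integer(n_S); ell <- as.integer(ell)
  if (L_S <= 0L || L_S >= L) stop("need 0 < L_S < L")
  if (ell < 1L) stop("ell must be >= 1")
  if (L <= ell) stop("transcript too short for one ribosome (L <= ell)")
  x <- seq_len(L)
  w <- ifelse(x <= L_S, n_S * (x - 1) / (L_S - 1), n_S)
  if (weights == "integer") w <- round(w)
  structure(
    list(L = L, L_S = L_S, n_S = n_S, ell = ell, w = w, weights = weights),
    class = "reporter_geometry"
  )
}

#' @export
print.reporter_geometry <- function(x, ...) {
  cat(sprintf(
    "SunTag reporter: L = %d codons, SunTag L_S = %d codons (%d epitopes, %s weights), footprint %d codons\n",
    x$L, x$L_S, x$n_S, x$weights, x$ell))
  invisible(x)
}

#' Kinetic parameters of the translation model
#'
#' Initiation rate `alpha` (1/s), uniform elongation rate `lam` (codons/s;
#' the termination rate is set equal to `lam`), and optional telegraph
#' (two-state bursting) rates: `k_on` switches the transcript from the
#' inactive to the active state, `k_off` from active to inactive.
#'
#' @param alpha initiation rate, 1/s (`>= 0`).
#' @param lam elongation rate, codons/s (`> 0`).
#' @param k_on,k_off optional telegraph switching rates, 1/s.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(alpha, lam, k_on = NULL, k_off = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(lam), length(lam) == 1L, lam > 0)
  telegraph <- !is.null(k_on) || !is.null(k_off)
  if (telegraph) {
    if (is.null(k_on) || is.null(k_off))
      stop("bursting requires both k_on and k_off")
    stopifnot(k_on > 0, k_off > 0)
  }
  structure(
    list(alpha = alpha, lam = lam,
         k_on = if (telegraph) k_on else NA_real_,
         k_off = if (telegraph) k_off else NA_real_,
         telegraph = telegraph),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("alpha = %.4g /s, lambda = %.4g codons/s", x$alpha, x$lam))
  if (x$telegraph)
    cat(sprintf(", telegraph k_on = %.4g /s, k_off = %.4g /s", x$k_on, x$k_off))
  cat("\n")
  invisible(x)
}

#' Observation noise and intensity calibration
#'
#' Fixed constants of the fluorescence readout: intensity offset `b0` (mean
#' intensity of untranslated spots), single mature-protein intensity `i_MP`
#' (fluorescence of one completed epitope array), and the baseline lognormal
#' scale `s0` of the multiplicative measurement noise.
#'
#' @param b0 intensity offset, a.u.
#' @param i_MP intensity of one mature protein, a.u.
#' @param s0 baseline lognormal noise scale (dimensionless).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(b0 = 6, i_MP = 14, s0 = 0.34) {
  stopifnot(b0 >= 0, i_MP > 0, s0 > 0)
  structure(list(b0 = b0, i_MP = i_MP, s0 = s0), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("b0 = %.3g a.u., i_MP = %.3g a.u., s0 = %.3g\n",
              x$b0, x$i_MP, x$s0))
  invisible(x)
}
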