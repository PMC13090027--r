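## Bayesian quantification of diffraction-limited spots in image patches:
## 2D Gaussian plus tilted-plane background, pixel noise fixed from the
## cytoplasmic background, MAP fit with Laplace intervals.

#' Flat-field and dark-current correction
#'
#' `C = (O - DC) / (FF - DC) * mean(FF - DC)`, with the mean over all
#' pixels: divides out the illumination profile while preserving the overall
#' intensity scale.
#'
#' @param image observed image (matrix).
#' @param flatfield flat-field image.
#' @param darkcurrent dark-current image.
#' @export
flatfield_correct <- function(image, flatfield, darkcurrent) {
  stopifnot(all(dim(image) == dim(flatfield)),
            all(dim(image) == dim(darkcurrent)))
  denom <- flatfield - darkcurrent
  if (any(denom <= 0))
    stop("flat-field minus dark-current has non-positive pixels")
  (image - darkcurrent) / denom * mean(denom)
}

#' Priors for single-spot fitting
#'
#' Center priors are normal around the tracked spot position with sd 0.2 um;
#' the width prior is a narrow inverse-gamma (given as mean and sd, converted
#' internally to shape/scale); the total intensity has a half-normal prior;
#' the background level is normal with moments from cytoplasm statistics and
#' the plane tilts are zero-centred normals.
#'
#' @param x_r,y_r tracked spot center, um (patch-centred coordinates).
#' @param center_sd center prior sd, um.
#' @param width_mean,width_sd inverse-gamma prior moments for the spot
#'   width, um.
#' @param intensity_sd half-normal scale for the total intensity, a.u.
#' @param bg_mean,bg_sd background-level prior, a.u.
#' @param tilt_sd background tilt prior sd, a.u./um.
#' @export
spot_priors <- function(x_r = 0, y_r = 0, center_sd = 0.2,
                        width_mean = 0.20, width_sd = 0.02,
                        intensity_sd = 1000, bg_mean = 0, bg_sd = 10,
                        tilt_sd = 50) {
  stopifnot(center_sd > 0, width_mean > 0, width_sd > 0, intensity_sd > 0,
            bg_sd > 0, tilt_sd > 0)
  shape <- (width_mean / width_sd)^2 + 2
  scale <- width_mean * (shape - 1)
  structure(list(x_r = x_r, y_r = y_r, center_sd = center_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 width_shape = shape, width_scale = scale,
                 intensity_sd = intensity_sd, bg_mean = bg_mean,
                 bg_sd = bg_sd, tilt_sd = tilt_sd),
            class = "spot_priors")
}

## pixel-center coordinate grids for a square patch (origin at the center)
patch_grid <- function(extent, pixel_size) {
  n <- max(3L, round(extent / pixel_size))
  centers <- (seq_len(n) - (n + 1) / 2) * pixel_size
  list(n = n, x = matrix(centers, n, n, byrow = TRUE),
       y = matrix(centers, n, n))
}

## expected pixel values: integrated 2D Gaussian mass per pixel (so the
## summed spot equals I_tot) plus the tilted-plane background
spot_mu <- function(I_tot, x0, y0, w, a, b, c0, grid, pixel_size,
                    integrate_pixels = TRUE) {
  if (integrate_pixels) {
    h <- pixel_size / 2
    mx <- stats::pnorm(grid$x + h, x0, w) - stats::pnorm(grid$x - h, x0, w)
    my <- stats::pnorm(grid$y + h, y0, w) - stats::pnorm(grid$y - h, y0, w)
    gauss <- I_tot * mx * my
  } else {
    gauss <- I_tot * pixel_size^2 / (2 * pi * w^2) *
      exp(-((grid$x - x0)^2 + (grid$y - y0)^2) / (2 * w^2))
  }
  gauss + c0 + a * (grid$x - x0) + b * (grid$y - y0)
}

#' Synthesize a noisy single-spot image patch
#'
#' Generates a square patch with an integrated 2D Gaussian spot on a tilted
#' plane and i.i.d. Gaussian pixel noise; the fixture generator for testing
#' [fit_spot()].
#'
#' @param I_tot total spot intensity, a.u.
#' @param x0,y0 spot center, um (patch-centred coordinates).
#' @param w_spot Gaussian width, um.
#' @param a,b background tilt coefficients, a.u./um.
#' @param c0 background level, a.u.
#' @param sigma_px pixel noise sd, a.u.
#' @param extent patch side length, um.
#' @param pixel_size pixel size, um (16-um camera pixels through a 60x
#'   objective give ~0.27 um).
#' @param seed optional integer seed.
#' @return A matrix of pixel values with attributes `x` and `y` (pixel
#'   center coordinates).
#' @export
synth_patch <- function(I_tot, x0 = 0, y0 = 0, w_spot = 0.2, a = 0, b = 0,
                        c0 = 0, sigma_px = 1, extent = 2, pixel_size = 0.27,
                        seed = NULL) {
  stopifnot(I_tot >= 0, w_spot > 0, sigma_px >= 0)
  if (!is.null(seed)) set.seed(seed)
  grid <- patch_grid(extent, pixel_size)
  mu <- spot_mu(I_tot, x0, y0, w_spot, a, b, c0, grid, pixel_size)
  patch <- mu + rnorm(length(mu), 0, sigma_px)
  dim(patch) <- dim(mu)
  attr(patch, "x") <- grid$x
  attr(patch, "y") <- grid$y
  attr(patch, "pixel_size") <- pixel_size
  patch
}

#' Fit the single-spot model to an image patch
#'
#' MAP estimation of the 2D-Gaussian-plus-tilted-plane model under the
#' priors of [spot_priors()], with the pixel noise sd fixed (estimated
#' upstream from the cytoplasmic background).  Intervals come from the
#' observed information at the mode (Laplace approximation).
#'
#' @param patch pixel matrix (e.g. from [synth_patch()] or a TIFF patch).
#' @param priors a [spot_priors()].
#' @param sigma_px fixed pixel noise sd, a.u.
#' @param pixel_size pixel size, um.
#' @return An object of class `spot_fit`: data.frame `estimates`
#'   (`I_tot`, `x0`, `y0`, `w_spot`, `a`, `b`, `c`) with 95% intervals,
#'   and the achieved log posterior.
#' @export
fit_spot <- function(patch, priors, sigma_px, pixel_size = 0.27) {
  stopifnot(inherits(priors, "spot_priors"), sigma_px > 0)
  n <- nrow(patch)
  extent <- n * pixel_size
  grid <- patch_grid(extent, pixel_size)
  yv <- as.numeric(patch)

  neglogpost <- function(p) {
    I_tot <- p[1]; x0 <- p[2]; y0 <- p[3]; w <- p[4]
    a <- p[5]; b <- p[6]; c0 <- p[7]
    mu <- spot_mu(I_tot, x0, y0, w, a, b, c0, grid, pixel_size)
    nll <- sum((yv - as.numeric(mu))^2) / (2 * sigma_px^2)
    npr <- I_tot^2 / (2 * priors$intensity_sd^2) -
      dnorm(x0, priors$x_r, priors$center_sd, log = TRUE) -
      dnorm(y0, priors$y_r, priors$center_sd, log = TRUE) -
      ((-(priors$width_shape + 1)) * log(w) - priors$width_scale / w) -
      dnorm(c0, priors$bg_mean, priors$bg_sd, log = TRUE) -
      dnorm(a, 0, priors$tilt_sd, log = TRUE) -
      dnorm(b, 0, priors$tilt_sd, log = TRUE)
    nll + npr
  }

  c_start <- stats::median(yv)
  I_start <- max(sum(yv - c_start), 1)
  p0 <- c(I_start, priors$x_r, priors$y_r, priors$width_mean, 0, 0, c_start)
  lower <- c(0, priors$x_r - 1, priors$y_r - 1, 0.05, -Inf, -Inf, -Inf)
  upper <- c(Inf, priors$x_r + 1, priors$y_r + 1, 1.5, Inf, Inf, Inf)
  res <- optim(p0, neglogpost, method = "L-BFGS-B", lower = lower,
               upper = upper, control = list(maxit = 500))
  H <- tryCatch(optimHess(res$par, neglogpost), error = function(e) NULL)
  se <- rep(NA_real_, 7)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  nm <- c("I_tot", "x0", "y0", "w_spot", "a", "b", "c")
  est <- data.frame(param = nm, estimate = res$par,
                    lower = res$par - 1.96 * se,
                    upper = res$par + 1.96 * se)
  # MAP on the I_tot >= 0 boundary: the quadratic approximation is one-sided
  if (res$par[1] < 1e-6) est$lower[1] <- 0
  est$lower[1] <- max(0, est$lower[1])
  structure(list(estimates = est, logpost = -res$value,
                 convergence = res$convergence),
            class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  df <- x$estimates
  df[, -1] <- signif(df[, -1], 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extrapolate spot intensity to the imaging laser power
#'
#' Spot intensity is linear in laser power; fits an ordinary linear
#' regression through calibration measurements and predicts the intensity
#' (with a 95% confidence interval) at the target power.
#'
#' @param power laser powers of the calibration acquisitions.
#' @param intensity measured spot intensities, a.u.
#' @param target_power power at which to predict, same units as `power`.
#' @return A list with `fit` (the `lm`), `prediction` (fit, lwr, upr at the
#'   target power).
#' @export
power_calibration <- function(power, intensity, target_power) {
  stopifnot(length(power) == length(intensity), length(power) >= 2)
  fit <- lm(intensity ~ power)
  pred <- predict(fit, newdata = data.frame(power = target_power),
                  interval = "confidence")
  list(fit = fit, prediction = as.data.frame(pred))
}

#' Read a (multi-frame) TIFF patch
#'
#' @param path TIFF file path.
#' @return A pixel matrix, or a list of matrices for a multi-frame file.
#' @export
read_patch_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF patches requires the 'tiff' package")
  img <- tiff::readTIFF(path, all = TRUE)
  if (is.list(img) && length(img) == 1L) img[[1]] else img
}
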