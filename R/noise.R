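#' Poisson-Gaussian acquisition parameters
#'
#' Bundle of the parameters of the mixed Poisson-Gaussian noise model of a
#' fluorescence detector: the observed image is
#' \deqn{V = g_0 \, \mathrm{Poisson}(U) + \mathcal{N}(m, \sigma_\varepsilon^2),}
#' where \eqn{U} is the (non-negative) expected photon image, \eqn{g_0} the
#' detector gain, and the additive Gaussian term models dark current and
#' readout noise.
#'
#' @param g0 detector gain, dimensionless, strictly positive.
#' @param m mean of the additive Gaussian component (intensity units).
#' @param sigma_eps standard deviation of the additive Gaussian component,
#'   non-negative.
#' @return An object of class `noise_params`.
#' @examples
#' noise_params(g0 = 1, m = 12, sigma_eps = 0.5)
#' @export
noise_params <- function(g0 = 1, m = 0, sigma_eps = 0) {
  stopifnot_scalar(g0, "g0"); stopifnot_scalar(m, "m")
  stopifnot_scalar(sigma_eps, "sigma_eps")
  if (g0 <= 0) stop("'g0' must be > 0", call. = FALSE)
  if (sigma_eps < 0) stop("'sigma_eps' must be >= 0", call. = FALSE)
  structure(list(g0 = as.numeric(g0), m = as.numeric(m),
                 sigma_eps = as.numeric(sigma_eps)),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("Poisson-Gaussian noise parameters: g0 = %g, m = %g, sigma_eps = %g\n",
              x$g0, x$m, x$sigma_eps))
  invisible(x)
}

#' Forward Poisson-Gaussian degradation
#'
#' Simulates the acquisition of a noise-free photon image by a detector with
#' gain `g0` and additive Gaussian noise: each pixel is drawn independently
#' as `g0 * rpois(1, u) + rnorm(1, m, sigma_eps)`.
#'
#' @param truth numeric matrix of non-negative expected photon counts.
#' @param params a [noise_params()] object.
#' @param seed optional integer seed; with a fixed seed the output is
#'   bit-reproducible.
#' @return Numeric matrix with the same dimensions as `truth`.
#' @examples
#' v <- degrade(matrix(50, 10, 10), noise_params(m = 12, sigma_eps = 0.5),
#'              seed = 1)
#' @export
degrade <- function(truth, params = noise_params(), seed = NULL) {
  truth <- as_image(truth, "truth")
  if (!inherits(params, "noise_params")) stop("'params' must be a noise_params object")
  if (any(truth < 0)) stop("'truth' must be non-negative", call. = FALSE)
  set_seed_if(seed)
  n <- length(truth)
  v <- params$g0 * rpois(n, lambda = as.vector(truth)) +
    rnorm(n, mean = params$m, sd = params$sigma_eps)
  matrix(v, nrow = nrow(truth), ncol = ncol(truth))
}

# Constant term inside the generalized Anscombe root.
gat_const <- function(params) {
  (3 / 8) * params$g0^2 + params$sigma_eps^2 - params$g0 * params$m
}

#' Generalized Anscombe variance-stabilizing transform
#'
#' Maps an observation contaminated by Poisson-Gaussian noise (see
#' [degrade()]) to a domain in which the noise is approximately Gaussian
#' with unit variance:
#' \deqn{T(v) = \frac{2}{g_0}\sqrt{g_0 v + \tfrac{3}{8} g_0^2 +
#'   \sigma_\varepsilon^2 - g_0 m}.}
#' The argument of the square root is clamped at zero, so the transform is
#' total and monotone non-decreasing; it never produces `NaN`.
#'
#' @param observed numeric matrix (or vector) of detector counts.
#' @inheritParams degrade
#' @return Transformed values, same shape as the input.
#' @seealso [vst_inverse()]
#' @export
vst_forward <- function(observed, params = noise_params()) {
  if (!inherits(params, "noise_params")) stop("'params' must be a noise_params object")
  inner <- params$g0 * observed + gat_const(params)
  (2 / params$g0) * sqrt(pmax(inner, 0))
}

#' Inverse of the variance-stabilizing transform
#'
#' Algebraic inverse of [vst_forward()].  Transformed values below zero are
#' clamped to zero before inversion and results below zero photon
#' equivalents are clamped to zero, so `vst_inverse(vst_forward(v))`
#' recovers `v` exactly on the valid domain of the forward transform (where
#' its square-root argument is positive).
#'
#' @param transformed numeric matrix (or vector) in the stabilized domain.
#' @inheritParams degrade
#' @export
vst_inverse <- function(transformed, params = noise_params()) {
  if (!inherits(params, "noise_params")) stop("'params' must be a noise_params object")
  t0 <- pmax(transformed, 0)
  v <- (t0^2 * params$g0^2 / 4 - gat_const(params)) / params$g0
  pmax(v, 0)
}

#' Estimate noise parameters from a background region
#'
#' Estimates the additive Gaussian component of the acquisition model from a
#' photon-free background region of interest: `m` is the ROI sample mean and
#' `sigma_eps` the ROI sample standard deviation.  The gain cannot be
#' identified from a photon-free region and defaults to the supplied `g0`.
#'
#' @param image numeric matrix.
#' @param background a [roi()] giving the background region; must contain at
#'   least 100 pixels and lie inside the image.
#' @param g0 gain to record in the returned parameters (default 1).
#' @return A [noise_params()] object.
#' @export
estimate_background_noise <- function(image, background, g0 = 1) {
  image <- as_image(image)
  px <- roi_pixels(image, background)
  if (length(px) < 100L)
    stop("background ROI must contain at least 100 pixels", call. = FALSE)
  s <- if (length(px) > 1L) sd(px) else 0
  noise_params(g0 = g0, m = mean(px), sigma_eps = s)
}
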