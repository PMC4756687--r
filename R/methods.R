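#' @export
print.srf_denoise <- function(x, ...) {
  cat("SRF denoising fit\n")
  cat(sprintf("  image: %d x %d pixels\n", nrow(x$estimate), ncol(x$estimate)))
  cat(sprintf("  layers: %d (%s engine), neighbourhood %dx%d, region %dx%d\n",
              x$control$layers, x$engine, x$control$neighborhood,
              x$control$neighborhood, x$control$region, x$control$region))
  cat(sprintf("  Q = %g, sigma = %g, lambda = %g, step = %g\n",
              x$control$q, x$control$sigma, x$control$lambda, x$control$step))
  if (nrow(x$energy) > 0)
    cat(sprintf("  total energy: %.6g -> %.6g\n",
                x$energy$energy_pre[1], x$energy$energy_post[nrow(x$energy)]))
  invisible(x)
}

#' @export
summary.srf_denoise <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    dim = dim(object$estimate),
    control = object$control,
    noise = object$noise,
    engine = object$engine,
    energy = object$energy,
    descent = if (nrow(object$energy) > 0)
      all(object$energy$energy_post <= object$energy$energy_pre + 1e-9) else NA,
    residual_summary = summary(as.vector(res)))
  class(out) <- "summary.srf_denoise"
  out
}

#' @export
print.summary.srf_denoise <- function(x, ...) {
  cat(sprintf("SRF denoising fit: %d x %d image, %d layers (%s engine)\n",
              x$dim[1], x$dim[2], x$control$layers, x$engine))
  print(x$control)
  print(x$noise)
  if (!is.na(x$descent))
    cat(sprintf("  energy non-increasing at every layer: %s\n", x$descent))
  cat("  residuals (observed - estimate):\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
fitted.srf_denoise <- function(object, ...) object$estimate

#' Residuals of an SRF fit
#'
#' The difference between the observation and the denoised estimate on the
#' count scale.  Under the acquisition model these should look like
#' (signal-dependent) Poisson-Gaussian noise around `m`.
#'
#' @param object an `srf_denoise` object.
#' @param ... ignored.
#' @export
residuals.srf_denoise <- function(object, ...) object$observed - object$estimate

#' @export
coef.srf_denoise <- function(object, ...) {
  c(q = object$control$q, sigma = object$control$sigma,
    layers = object$control$layers, lambda = object$control$lambda,
    step = object$control$step, neighborhood = object$control$neighborhood,
    region = object$control$region)
}

#' Simulate new acquisitions from a fitted SRF model
#'
#' Treats the denoised estimate as the expected photon image and draws new
#' observations from the fitted Poisson-Gaussian acquisition model via
#' [degrade()].
#'
#' @param object an `srf_denoise` object.
#' @param nsim number of replicate images.
#' @param seed optional seed.
#' @param ... ignored.
#' @return A list of `nsim` matrices.
#' @export
simulate.srf_denoise <- function(object, nsim = 1, seed = NULL, ...) {
  set_seed_if(seed)
  truth <- pmax(object$estimate, 0)
  lapply(seq_len(nsim), function(i) degrade(truth, object$noise, seed = NULL))
}

#' Plot an SRF fit
#'
#' Grey-scale panels of the observation, the denoised estimate and the
#' residual image, on a shared intensity scale for the first two.
#'
#' @param x an `srf_denoise` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.srf_denoise <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  zl <- range(x$observed, x$estimate)
  show <- function(img, main, zlim = NULL) {
    img <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
    graphics::image(img, axes = FALSE, asp = nrow(x$observed) / ncol(x$observed),
                    col = grDevices::gray.colors(256, start = 0, end = 1),
                    main = main, zlim = if (is.null(zlim)) range(img) else zlim, ...)
  }
  show(x$observed, "observed", zl)
  show(x$estimate, "SRF estimate", zl)
  show(residuals(x), "residuals")
  invisible(x)
}
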