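#' Rectangular region of interest
#'
#' Axis-aligned rectangle in 0-based, top-left-origin pixel coordinates
#' with half-open extent: it covers rows `y .. y+h-1` and columns
#' `x .. x+w-1` of the image.
#'
#' @param x,y 0-based column and row of the top-left pixel.
#' @param w,h extent in pixels, `w * h >= 1`.
#' @return An object of class `roi`.
#' @export
roi <- function(x, y, w, h) {
  vals <- c(x = x, y = y, w = w, h = h)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stop("ROI coordinates must be integers", call. = FALSE)
  if (x < 0 || y < 0 || w < 1 || h < 1)
    stop("ROI must have non-negative origin and positive extent", call. = FALSE)
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI: x = %d, y = %d, w = %d, h = %d (0-based, top-left origin)\n",
              x$x, x$y, x$w, x$h))
  invisible(x)
}

# Pixels of an image inside an ROI, validating bounds.
roi_pixels <- function(image, r) {
  if (!inherits(r, "roi")) stop("expected an 'roi' object", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  if (r$y + r$h > h || r$x + r$w > w)
    stop("ROI extends outside the image", call. = FALSE)
  as.vector(image[(r$y + 1L):(r$y + r$h), (r$x + 1L):(r$x + r$w)])
}

check_same_dim <- function(a, b, na, nb) {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("'%s' and '%s' dimensions differ", na, nb), call. = FALSE)
}

mse <- function(a, b) mean((a - b)^2)

#' Signal-to-noise ratio against ground truth (dB)
#'
#' `10 log10( sum(u^2) / sum((u - uhat)^2) )`: the power ratio of the true
#' signal to the estimation error.
#'
#' @param truth,estimate numeric matrices of equal dimension.
#' @return Decibels; `Inf` when the estimate equals the truth exactly.
#' @export
snr_db <- function(truth, estimate) {
  truth <- as_image(truth, "truth"); estimate <- as_image(estimate, "estimate")
  check_same_dim(truth, estimate, "truth", "estimate")
  sig <- sum(truth^2)
  if (sig == 0) stop("'truth' is identically zero; SNR undefined", call. = FALSE)
  err <- sum((truth - estimate)^2)
  if (err == 0) return(Inf)
  10 * log10(sig / err)
}

#' Improvement in SNR (dB)
#'
#' `10 log10( MSE(noisy, truth) / MSE(denoised, truth) )`: positive when
#' the denoiser moved the image closer to the truth, 0 dB for the identity
#' denoiser.
#'
#' @param truth,noisy,denoised numeric matrices of equal dimension.
#' @export
isnr_db <- function(truth, noisy, denoised) {
  truth <- as_image(truth, "truth"); noisy <- as_image(noisy, "noisy")
  denoised <- as_image(denoised, "denoised")
  check_same_dim(truth, noisy, "truth", "noisy")
  check_same_dim(truth, denoised, "truth", "denoised")
  md <- mse(denoised, truth)
  if (md == 0) return(Inf)
  10 * log10(mse(noisy, truth) / md)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10( max_value^2 / MSE(truth, estimate) )` with `max_value`
#' defaulting to 255 for an 8-bit ground truth.
#'
#' @inheritParams snr_db
#' @param max_value maximum possible data value, > 0.
#' @export
psnr_db <- function(truth, estimate, max_value = 255) {
  truth <- as_image(truth, "truth"); estimate <- as_image(estimate, "estimate")
  check_same_dim(truth, estimate, "truth", "estimate")
  stopifnot_scalar(max_value, "max_value")
  if (max_value <= 0) stop("'max_value' must be > 0", call. = FALSE)
  m <- mse(truth, estimate)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Empirical ROI-based SNR (dB)
#'
#' `20 log10( mean(cell) / sd(background) )`, usable without ground truth:
#' the cell region supplies the signal amplitude and a smooth background
#' region the noise level.  Amplitude ratios use the factor 20.
#'
#' @param image numeric matrix.
#' @param cell,background [roi()] objects inside the image.
#' @export
roi_snr_db <- function(image, cell, background) {
  image <- as_image(image)
  mc <- mean(roi_pixels(image, cell))
  sb <- sd(roi_pixels(image, background))
  if (mc <= 0) stop("cell ROI mean must be > 0 for SNR in dB", call. = FALSE)
  if (sb == 0) return(Inf)
  20 * log10(mc / sb)
}

#' Empirical contrast-to-noise ratio (dB)
#'
#' `20 log10( |mean(cell) - mean(background)| / sd(background) )`.
#'
#' @inheritParams roi_snr_db
#' @return Decibels; `-Inf` when the two region means are equal, `Inf`
#'   when the background has zero variance.
#' @export
roi_cnr_db <- function(image, cell, background) {
  image <- as_image(image)
  mc <- mean(roi_pixels(image, cell))
  mb <- mean(roi_pixels(image, background))
  sb <- sd(roi_pixels(image, background))
  if (sb == 0) return(Inf)
  if (mc == mb) return(-Inf)
  20 * log10(abs(mc - mb) / sb)
}

#' Evaluate one denoising run
#'
#' Computes every applicable metric for one (truth, noisy, denoised)
#' triple, plus ROI metrics when regions are supplied.
#'
#' @param denoised denoised image (matrix).
#' @param truth,noisy optional ground truth and noisy observation.
#' @param max_value peak value for [psnr_db()].
#' @param cell,background optional [roi()]s for the empirical metrics.
#' @param run run index recorded in the output.
#' @return Data frame with columns `metric`, `value_db`, `run`.
#' @export
evaluate_images <- function(denoised, truth = NULL, noisy = NULL,
                            max_value = 255, cell = NULL, background = NULL,
                            run = 1L) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value_db = value,
                                             run = as.integer(run))
  if (!is.null(truth)) {
    add("snr", snr_db(truth, denoised))
    add("psnr", psnr_db(truth, denoised, max_value))
    if (!is.null(noisy)) {
      add("isnr", isnr_db(truth, noisy, denoised))
      add("psnr_noisy", psnr_db(truth, noisy, max_value))
    }
  }
  if (!is.null(cell) && !is.null(background)) {
    add("roi_snr", roi_snr_db(denoised, cell, background))
    add("roi_cnr", roi_cnr_db(denoised, cell, background))
  }
  if (!length(rows))
    return(data.frame(metric = character(), value_db = numeric(), run = integer()))
  do.call(rbind, rows)
}

#' Aggregate metric reports over repeated runs
#'
#' Per-metric arithmetic mean and sample standard deviation across runs,
#' mirroring a run-it-30-times-and-average evaluation protocol for a
#' stochastic algorithm.  Non-finite values (the `Inf` sentinels of exact
#' reconstructions) are excluded and counted.
#'
#' @param reports a data frame as returned by [evaluate_images()]
#'   (possibly `rbind`-ed over runs), or a list of such data frames.
#' @return Data frame with columns `metric`, `mean_db`, `sd_db` (`NA` for
#'   fewer than two finite values), `n`, `n_excluded`.
#' @export
aggregate_runs <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (!length(reports)) stop("'reports' must be non-empty", call. = FALSE)
  all_rows <- do.call(rbind, reports)
  out <- lapply(split(all_rows, all_rows$metric), function(d) {
    v <- d$value_db
    fin <- v[is.finite(v)]
    data.frame(metric = d$metric[1],
               mean_db = if (length(fin)) mean(fin) else NA_real_,
               sd_db = if (length(fin) >= 2) sd(fin) else NA_real_,
               n = length(fin), n_excluded = sum(!is.finite(v)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a metric report to CSV
#'
#' Serializes per-run and aggregate metrics; infinite values are written as
#' the strings `"inf"` / `"-inf"`, never as numbers.  A header comment
#' records the dB conventions (factor 10 for the power-ratio metrics SNR,
#' ISNR and PSNR; factor 20 for the amplitude-ratio ROI metrics).
#'
#' @param report per-run data frame from [evaluate_images()].
#' @param path output CSV path.
#' @export
write_report <- function(report, path) {
  agg <- aggregate_runs(report)
  fmt <- function(v) ifelse(is.finite(v), format(v, digits = 10),
                            ifelse(v > 0, "inf", "-inf"))
  per_run <- data.frame(metric = report$metric, value_db = fmt(report$value_db),
                        run = report$run, aggregate = "")
  agg_rows <- data.frame(metric = agg$metric, value_db = fmt(agg$mean_db),
                         run = NA_integer_, aggregate = "mean")
  sd_rows <- data.frame(metric = agg$metric,
                        value_db = ifelse(is.na(agg$sd_db), "",
                                          format(agg$sd_db, digits = 10)),
                        run = NA_integer_, aggregate = "sd")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# dB conventions: 10*log10 for SNR/ISNR/PSNR (power),",
                   "20*log10 for ROI SNR/CNR (amplitude)"), con)
  write.csv(rbind(per_run, agg_rows, sd_rows), con, row.names = FALSE)
  invisible(path)
}
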