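#' Run the SRF denoiser, possibly repeatedly and per channel
#'
#' End-to-end driver: denoises each channel of the observation for each of
#' `runs` repetitions (per-run seeds are `seed + run_index - 1`), computes
#' metrics when ground truth is available, and optionally writes per-run
#' and mean output images.
#'
#' @param observed a matrix, a list of matrices (channels), or a path read
#'   with [read_image()].
#' @param noise a [noise_params()] object, or a list of one per channel.
#' @param control an [srf_control()] object; its seed field is overridden
#'   by the derived per-run seed.
#' @param truth optional ground truth (matrix / list / path) enabling
#'   SNR/ISNR/PSNR.
#' @param runs number of repetitions (a stochastic-algorithm evaluation
#'   protocol would use 30).
#' @param seed master seed.
#' @param background optional [roi()]: photon-free region used to estimate
#'   the per-channel smoothness constant.
#' @param cell optional [roi()] for empirical ROI metrics (with
#'   `background`).
#' @param max_value peak value for PSNR (default 255).
#' @param offset known additive intensity offset (for instance the
#'   dark-current mean) subtracted from the noisy and denoised images
#'   before comparing with the photon-scale ground truth; default 0.
#' @param out optional directory to write `denoised_run<r>.tif` (channels
#'   as pages) and `denoised_mean.tif`.
#' @return An object of class `srf_run`: list with `report` (per-run,
#'   per-channel metric rows), `aggregate`, `mean_estimate` (list of
#'   channel matrices averaged over runs), `seeds` and the echoed
#'   configuration.
#' @export
run_denoise <- function(observed, noise = noise_params(),
                        control = srf_control(), truth = NULL, runs = 1,
                        seed = 1, background = NULL, cell = NULL,
                        max_value = 255, offset = 0, out = NULL) {
  if (is.character(observed)) observed <- read_image(observed)
  if (!is.list(observed)) observed <- list(observed)
  observed <- lapply(observed, as_image)
  if (!is.null(truth)) {
    if (is.character(truth)) truth <- read_image(truth)
    if (!is.list(truth)) truth <- list(truth)
    if (length(truth) != length(observed))
      stop("'truth' must have one channel per observed channel", call. = FALSE)
  }
  noise_list <- if (inherits(noise, "noise_params"))
    rep(list(noise), length(observed)) else noise
  if (length(noise_list) != length(observed))
    stop("'noise' must be one noise_params or one per channel", call. = FALSE)
  runs <- as.integer(runs)
  if (is.na(runs) || runs < 1L) stop("'runs' must be >= 1", call. = FALSE)
  seeds <- as.integer(seed) + seq_len(runs) - 1L
  reports <- list()
  sums <- lapply(observed, function(x) matrix(0, nrow(x), ncol(x)))
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  for (r in seq_len(runs)) {
    run_channels <- vector("list", length(observed))
    for (ch in seq_along(observed)) {
      ctrl <- control
      ctrl$seed <- seeds[r]
      fit <- srf_denoise(observed[[ch]], noise_list[[ch]], ctrl,
                         background = background)
      run_channels[[ch]] <- fitted(fit)
      sums[[ch]] <- sums[[ch]] + fitted(fit)
      rep_r <- evaluate_images(fitted(fit) - offset,
                               truth = if (is.null(truth)) NULL else truth[[ch]],
                               noisy = observed[[ch]] - offset,
                               max_value = max_value,
                               cell = cell, background = background, run = r)
      if (nrow(rep_r)) {
        rep_r$channel <- ch
        reports[[length(reports) + 1L]] <- rep_r
      }
    }
    if (!is.null(out)) {
      write_image(run_channels, file.path(out, sprintf("denoised_run%d.tif", r)))
    }
  }
  mean_estimate <- lapply(sums, function(s) s / runs)
  if (!is.null(out)) write_image(mean_estimate, file.path(out, "denoised_mean.tif"))
  report <- if (length(reports)) do.call(rbind, reports) else
    data.frame(metric = character(), value_db = numeric(), run = integer(),
               channel = integer())
  structure(list(report = report,
                 aggregate = if (nrow(report)) aggregate_runs(report) else NULL,
                 mean_estimate = mean_estimate, seeds = seeds,
                 control = control, noise = noise_list, runs = runs),
            class = "srf_run")
}

#' @export
print.srf_run <- function(x, ...) {
  cat(sprintf("SRF run: %d run(s), %d channel(s), seeds %d..%d\n",
              x$runs, length(x$mean_estimate), x$seeds[1], x$seeds[x$runs]))
  if (!is.null(x$aggregate)) print(x$aggregate)
  invisible(x)
}

#' Grid-search tuning of the SRF parameters
#'
#' Evaluates every point of a Cartesian parameter grid on a dataset with
#' ground truth, scoring each point by the mean objective over `runs`
#' seeded repetitions, and returns the best control plus a leaderboard
#' sorted by decreasing objective.  Ties are broken towards fewer layers,
#' then smaller lambda, Q and sigma, for reproducibility.
#'
#' @param grid named list with any of `q`, `sigma`, `layers`, `lambda`;
#'   each entry a vector of candidate values.  The Cartesian product is
#'   evaluated.
#' @param truth,noisy ground-truth and noisy images (matrices), or lists
#'   of paired matrices for a multi-image tuning subset.
#' @param noise a [noise_params()] object.
#' @param control base [srf_control()] supplying the parameters not in the
#'   grid.
#' @param objective `"psnr"` or `"snr"`, maximized.
#' @param runs seeded repetitions per grid point.
#' @param seed master seed (per-run seeds are `seed + run - 1`).
#' @param max_value peak value for PSNR.
#' @param offset known additive intensity offset subtracted from the
#'   denoised image before scoring against the photon-scale truth.
#' @return List with `best` (an [srf_control()]), `leaderboard` (data
#'   frame, one row per grid point) and `objective`.
#' @export
tune_srf <- function(grid, truth, noisy, noise = noise_params(),
                     control = srf_control(), objective = c("psnr", "snr"),
                     runs = 1, seed = 1, max_value = 255, offset = 0) {
  objective <- match.arg(objective)
  allowed <- c("q", "sigma", "layers", "lambda")
  if (!is.list(grid) || !length(grid) || !all(names(grid) %in% allowed))
    stop("'grid' must be a named list over q, sigma, layers, lambda", call. = FALSE)
  if (!is.list(truth)) truth <- list(truth)
  if (!is.list(noisy)) noisy <- list(noisy)
  if (length(truth) != length(noisy))
    stop("'truth' and 'noisy' must pair up", call. = FALSE)
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  message(sprintf("tune: evaluating %d grid point(s) x %d run(s) x %d image(s)",
                  nrow(points), as.integer(runs), length(truth)))
  scores <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    ctrl <- control
    for (nm in names(points)) ctrl[[nm]] <- points[[nm]][i]
    if (!"q" %in% names(points) && "sigma" %in% names(points))
      ctrl$q <- ctrl$sigma  # keep flexibility tied to smoothness
    vals <- numeric(0)
    for (r in seq_len(runs)) {
      ctrl$seed <- as.integer(seed) + r - 1L
      for (d in seq_along(truth)) {
        fit <- srf_denoise(noisy[[d]], noise, ctrl)
        est <- fitted(fit) - offset
        vals <- c(vals, if (objective == "psnr")
          psnr_db(truth[[d]], est, max_value)
          else snr_db(truth[[d]], est))
      }
    }
    scores[i] <- mean(vals)
  }
  lb <- cbind(points, objective_db = scores)
  tie_cols <- intersect(c("layers", "lambda", "q", "sigma"), names(points))
  ord <- do.call(order, c(list(-scores), lapply(tie_cols, function(nm) lb[[nm]])))
  lb <- lb[ord, , drop = FALSE]
  rownames(lb) <- NULL
  best <- control
  for (nm in names(points)) best[[nm]] <- lb[[nm]][1]
  if (!"q" %in% names(points) && "sigma" %in% names(points)) best$q <- best$sigma
  list(best = best, leaderboard = lb, objective = objective)
}
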