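#' Specification of the synthetic fluorescence-microscopy phantom
#'
#' Parameters of the procedural phantom and of its simulated acquisition:
#' sparse elliptical cells with brighter membrane rims and small bright
#' nucleoli foci on a dark background, plus diffuse autofluorescence
#' background profiles, imaged through a photon-conversion factor `beta`
#' and detector dark current.
#'
#' @param size integer `c(height, width)` (default 256 x 256).
#' @param n_cells number of cells; default scales with image area so about
#'   a tenth of the image is covered.
#' @param n_profiles number of Gaussian autofluorescence profiles added to
#'   the background (default 200).
#' @param profile_amp_max maximum profile peak amplitude in photons
#'   (default 20; amplitudes are uniform in `[0, profile_amp_max]`).
#' @param profile_sigma_range range of profile widths in pixels (default
#'   `c(2, 12)`).
#' @param beta photon-conversion factor in `(0, 1]`: the Poisson mean of
#'   the detected photons is `beta * truth`, so small `beta` means a
#'   photon-starved (noisy) acquisition.
#' @param dark_mean,dark_std mean and standard deviation of the additive
#'   Gaussian dark current (defaults 12 and 0.5).
#' @param base optional path to a grayscale image to use as the
#'   ground-truth photon image instead of the procedural one; it is
#'   quantized to 8 bits.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256, 256), n_cells = NULL, n_profiles = 200,
                         profile_amp_max = 20, profile_sigma_range = c(2, 12),
                         beta = 0.5, dark_mean = 12, dark_std = 0.5,
                         base = NULL) {
  size <- as.integer(size)
  if (length(size) != 2L || any(is.na(size)) || any(size < 8L))
    stop("'size' must be two integers >= 8", call. = FALSE)
  if (is.null(n_cells)) {
    r_mean <- 0.045 * min(size)
    n_cells <- max(3L, as.integer(round(0.10 * prod(size) / (pi * r_mean^2))))
  }
  n_cells <- as.integer(n_cells)
  n_profiles <- as.integer(n_profiles)
  if (n_profiles < 0L) stop("'n_profiles' must be >= 0", call. = FALSE)
  stopifnot_scalar(profile_amp_max, "profile_amp_max")
  if (length(profile_sigma_range) != 2L || any(profile_sigma_range <= 0) ||
      diff(profile_sigma_range) < 0)
    stop("'profile_sigma_range' must be an increasing positive pair", call. = FALSE)
  stopifnot_scalar(beta, "beta")
  if (beta <= 0 || beta > 1) stop("'beta' must be in (0, 1]", call. = FALSE)
  stopifnot_scalar(dark_mean, "dark_mean"); stopifnot_scalar(dark_std, "dark_std")
  if (dark_std < 0) stop("'dark_std' must be >= 0", call. = FALSE)
  structure(list(size = size, n_cells = n_cells, n_profiles = n_profiles,
                 profile_amp_max = as.numeric(profile_amp_max),
                 profile_sigma_range = as.numeric(profile_sigma_range),
                 beta = as.numeric(beta), dark_mean = as.numeric(dark_mean),
                 dark_std = as.numeric(dark_std), base = base),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("Phantom spec: %d x %d, %d cells, %d background profiles ",
                     "(amp <= %g, width %g-%g px),\n  beta = %g, dark current ",
                     "N(%g, %g^2)%s\n"),
              x$size[1], x$size[2], x$n_cells, x$n_profiles, x$profile_amp_max,
              x$profile_sigma_range[1], x$profile_sigma_range[2], x$beta,
              x$dark_mean, x$dark_std,
              if (is.null(x$base)) "" else sprintf(", base image '%s'", x$base)))
  invisible(x)
}

#' Ground-truth phantom image
#'
#' Draws the noise-free photon image: sparse elliptical cells (interior
#' intensity 60-120 photons) with a brighter membrane rim and 1-3 small
#' bright nucleoli foci (150-255 photons) per cell, on a zero background,
#' quantized to integers in `[0, 255]`.  With `spec$base` set, the file is
#' loaded and quantized to 8 bits instead.
#'
#' Random draws per cell, in order: centre row, centre column, the two
#' semi-axes, orientation, interior intensity, number of foci, then per
#' focus its radial position (fraction, angle), radius and amplitude.
#'
#' @param spec a [phantom_spec()] object.
#' @param seed optional seed; a fixed seed gives a bit-identical image.
#' @return Numeric matrix of integer-valued photon counts in `[0, 255]`.
#' @export
phantom_base <- function(spec = phantom_spec(), seed = NULL) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec object")
  if (!is.null(spec$base)) {
    img <- read_image(spec$base)
    if (is.list(img)) img <- img[[1L]]
    img <- img - min(img)
    if (max(img) > 0) img <- img / max(img) * 255
    return(round(img))
  }
  set_seed_if(seed)
  h <- spec$size[1]; w <- spec$size[2]
  img <- matrix(0, h, w)
  m <- min(h, w)
  r_lo <- 0.035 * m; r_hi <- 0.055 * m
  for (cell in seq_len(spec$n_cells)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    a <- runif(1, r_lo, r_hi); b <- runif(1, r_lo, r_hi)
    theta <- runif(1, 0, pi)
    interior <- runif(1, 60, 120)
    nfoci <- sample.int(3L, 1L)
    rmax <- max(a, b)
    rs <- max(1L, floor(cy - rmax - 1)):min(h, ceiling(cy + rmax + 1))
    cs <- max(1L, floor(cx - rmax - 1)):min(w, ceiling(cx + rmax + 1))
    yy <- outer(rs - cy, rep(1, length(cs)))
    xx <- outer(rep(1, length(rs)), cs - cx)
    xr <- cos(theta) * xx + sin(theta) * yy
    yr <- -sin(theta) * xx + cos(theta) * yy
    rho <- sqrt((xr / a)^2 + (yr / b)^2)
    patch <- img[rs, cs, drop = FALSE]
    val <- matrix(0, length(rs), length(cs))
    val[rho <= 1] <- interior
    val[rho > 0.80 & rho <= 1] <- min(interior * 1.6, 255)  # membrane rim
    img[rs, cs] <- pmax(patch, val)
    for (f in seq_len(nfoci)) {
      frac <- runif(1, 0, 0.6); ang <- runif(1, 0, 2 * pi)
      frad <- runif(1, 1, max(1.5, 0.15 * min(a, b)))
      famp <- runif(1, 150, 255)
      fy <- cy + frac * b * sin(ang); fx <- cx + frac * a * cos(ang)
      frs <- max(1L, floor(fy - frad)):min(h, ceiling(fy + frad))
      fcs <- max(1L, floor(fx - frad)):min(w, ceiling(fx + frad))
      dd <- outer((frs - fy)^2, rep(1, length(fcs))) +
        outer(rep(1, length(frs)), (fcs - fx)^2)
      fp <- img[frs, fcs, drop = FALSE]
      fp[dd <= frad^2] <- pmax(fp[dd <= frad^2], famp)
      img[frs, fcs] <- fp
    }
  }
  round(pmin(pmax(img, 0), 255))
}

#' Add autofluorescence background profiles
#'
#' Adds `spec$n_profiles` isotropic Gaussian intensity bumps with uniform
#' random centres, peak amplitudes uniform in `[0, profile_amp_max]`
#' photons and widths uniform in `profile_sigma_range` pixels, emulating
#' diffuse autofluorescence and stray fluorescent-tag accumulation.  The
#' output is everywhere at least the input.
#'
#' Random draws per profile, in order: centre row, centre column,
#' amplitude, width.  Each bump is evaluated on a window of +/- 4 widths.
#'
#' @param truth non-negative numeric matrix of photon counts.
#' @inheritParams phantom_base
#' @export
add_background_profiles <- function(truth, spec = phantom_spec(), seed = NULL) {
  truth <- as_image(truth, "truth")
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec object")
  if (any(truth < 0)) stop("'truth' must be non-negative", call. = FALSE)
  set_seed_if(seed)
  h <- nrow(truth); w <- ncol(truth)
  out <- truth
  for (p in seq_len(spec$n_profiles)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    amp <- runif(1, 0, spec$profile_amp_max)
    sg <- runif(1, spec$profile_sigma_range[1], spec$profile_sigma_range[2])
    ext <- ceiling(4 * sg)
    rs <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
    cs <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
    bump <- amp * exp(-(outer((rs - cy)^2, rep(1, length(cs))) +
                          outer(rep(1, length(rs)), (cs - cx)^2)) / (2 * sg^2))
    out[rs, cs] <- out[rs, cs] + bump
  }
  out
}

#' Simulate the acquisition of a phantom
#'
#' Photon arrival is Poisson with mean `beta * truth`; the recorded counts
#' are rescaled by `1 / beta` so all photon-conversion factors share the
#' intensity scale of the 8-bit ground truth, and Gaussian dark current
#' `N(dark_mean, dark_std^2)` is added:
#' \deqn{V = \mathrm{Poisson}(\beta U)/\beta + \mathcal{N}(m_d, s_d^2),}
#' so `E[V] = truth + dark_mean` and the Poisson noise variance scales as
#' `truth / beta` - smaller `beta` gives a noisier, photon-starved image.
#'
#' @inheritParams add_background_profiles
#' @return Numeric matrix of simulated detector counts.
#' @export
simulate_acquisition <- function(truth, spec = phantom_spec(), seed = NULL) {
  truth <- as_image(truth, "truth")
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec object")
  if (any(truth < 0)) stop("'truth' must be non-negative", call. = FALSE)
  set_seed_if(seed)
  n <- length(truth)
  v <- rpois(n, lambda = spec$beta * as.vector(truth)) / spec$beta +
    rnorm(n, mean = spec$dark_mean, sd = spec$dark_std)
  matrix(v, nrow = nrow(truth), ncol = ncol(truth))
}

#' Generate a phantom dataset across photon-conversion factors
#'
#' Builds one ground-truth image (procedural base plus background
#' profiles), shared bit-identically across the sweep, and one noisy
#' realization per `beta`.  With `dir` set, writes `gt.tif` and
#' `noisy_b<beta>.tif` as 32-bit float TIFFs plus a JSON manifest with the
#' spec, seed and file checksums.
#'
#' @param spec a [phantom_spec()] object (its `beta` field is ignored in
#'   favour of `betas`).
#' @param betas photon-conversion factors, each in `(0, 1]`.
#' @param seed master seed for the whole dataset.
#' @param dir optional output directory.
#' @return Invisibly, a list with `truth` (matrix), `noisy` (named list of
#'   matrices), `betas` and, when written, `files` and `manifest`.
#' @export
phantom_dataset <- function(spec = phantom_spec(), betas = seq(0.1, 0.9, by = 0.1),
                            seed = NULL, dir = NULL) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec object")
  if (!length(betas) || any(betas <= 0) || any(betas > 1))
    stop("'betas' must be a non-empty vector in (0, 1]", call. = FALSE)
  set_seed_if(seed)
  truth <- add_background_profiles(phantom_base(spec, seed = NULL), spec, seed = NULL)
  noisy <- list()
  for (b in betas) {
    sb <- spec; sb$beta <- b
    noisy[[sprintf("beta_%g", b)]] <- simulate_acquisition(truth, sb, seed = NULL)
  }
  out <- list(truth = truth, noisy = noisy, betas = betas)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gt_path <- file.path(dir, "gt.tif")
    write_image(truth, gt_path)
    files <- c(gt = gt_path)
    for (i in seq_along(betas)) {
      p <- file.path(dir, sprintf("noisy_b%g.tif", betas[i]))
      write_image(noisy[[i]], p)
      files[sprintf("noisy_b%g", betas[i])] <- p
    }
    manifest <- list(
      spec = unclass(spec)[setdiff(names(unclass(spec)), "base")],
      seed = seed, betas = betas,
      files = as.list(files),
      md5 = as.list(tools::md5sum(unname(files))))
    manifest_path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$files <- files
    out$manifest <- manifest_path
  }
  invisible(out)
}
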