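#' Read a TIFF or PNG image
#'
#' Integer data are returned on their native count scale (no rescaling to
#' `[0, 1]`): the variance-stabilizing transform operates on count-scale
#' values, so preserving scale is semantically required.  Multi-page TIFFs
#' and multi-channel pages are split into one matrix per channel, in file
#' order.  PNG values are rescaled by `2^bit.depth - 1` to recover the
#' stored integers.
#'
#' @param path file path; format is chosen by extension (`.tif`, `.tiff`,
#'   `.png`).
#' @return A numeric matrix for single-channel images, otherwise a list of
#'   matrices.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  channels <- list()
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
    # integer samples are read unscaled; float samples are stored as-is
    is_float <- "sample.format" %in% names(info) &&
      any(info[["sample.format"]] == "float")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
    if (!is.list(pages)) pages <- list(pages)
    for (pg in pages) {
      if (length(dim(pg)) == 3L) {
        for (ch in seq_len(dim(pg)[3])) {
          channels[[length(channels) + 1L]] <- as_image(pg[, , ch], require_finite = FALSE)
        }
      } else {
        channels[[length(channels) + 1L]] <- as_image(unclass(pg), require_finite = FALSE)
      }
    }
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    scale <- 2^depth - 1
    if (length(dim(img)) == 3L) {
      for (ch in seq_len(dim(img)[3])) {
        channels[[length(channels) + 1L]] <- as_image(img[, , ch] * scale,
                                                      require_finite = FALSE)
      }
    } else {
      channels[[length(channels) + 1L]] <- as_image(unclass(img) * scale,
                                                    require_finite = FALSE)
    }
  } else {
    stop(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext),
         call. = FALSE)
  }
  if (length(channels) == 1L) channels[[1L]] else channels
}

# Minimal uncompressed single-strip grayscale 32-bit float TIFF writer
# (little-endian, one IFD per page).  Written because the general-purpose
# TIFF writer available to the package stores only values in [0, 1], which
# cannot represent count-scale microscopy data; files produced here are
# read back by the standard TIFF reader.
write_tiff_float32 <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wr2(42L)
  n <- length(pages)
  data_off <- integer(n)
  pos <- 8L
  sizes <- vapply(pages, function(p) 4L * length(p), integer(1))
  for (i in seq_len(n)) { data_off[i] <- pos; pos <- pos + sizes[i] }
  ifd_size <- 2L + 10L * 12L + 4L
  ifd_off <- pos + ifd_size * (seq_len(n) - 1L)
  wr4(ifd_off[1])
  for (p in pages) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")  # row-major strips
  }
  entry <- function(tag, type, count, value) { wr2(tag); wr2(type); wr4(count); wr4(value) }
  SHORT <- 3L; LONG <- 4L
  for (i in seq_len(n)) {
    h <- nrow(pages[[i]]); w <- ncol(pages[[i]])
    wr2(10L)  # entry count
    entry(256L, LONG, 1L, w)            # ImageWidth
    entry(257L, LONG, 1L, h)            # ImageLength
    entry(258L, SHORT, 1L, 32L)         # BitsPerSample
    entry(259L, SHORT, 1L, 1L)          # Compression: none
    entry(262L, SHORT, 1L, 1L)          # Photometric: BlackIsZero
    entry(273L, LONG, 1L, data_off[i])  # StripOffsets
    entry(277L, SHORT, 1L, 1L)          # SamplesPerPixel
    entry(278L, LONG, 1L, h)            # RowsPerStrip
    entry(279L, LONG, 1L, sizes[i])     # StripByteCounts
    entry(339L, SHORT, 1L, 3L)          # SampleFormat: IEEE float
    wr4(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Write an image to TIFF or PNG
#'
#' The default policy stores 32-bit float TIFF on the native count scale,
#' which round-trips through [read_image()] to float precision.  Integer
#' export (`"uint16"`, `"uint8"`) clips to the representable range, with a
#' warning naming the number of clipped pixels, and rounds half to even.
#' PNG output supports only `"uint8"`.
#'
#' @param image numeric matrix, or list of matrices for a multi-page file.
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @param type `"float32"` (default, TIFF only), `"uint16"` or `"uint8"`.
#' @export
write_image <- function(image, path, type = c("float32", "uint16", "uint8")) {
  type <- match.arg(type)
  pages <- if (is.list(image)) image else list(image)
  pages <- lapply(pages, as_image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (type == "float32")
      stop("PNG output requires an integer type ('uint8')", call. = FALSE)
    if (type != "uint8") stop("PNG output supports only 'uint8'", call. = FALSE)
    if (length(pages) > 1L) stop("PNG output supports a single page", call. = FALSE)
    q <- quantize(pages[[1L]], 8L)
    png::writePNG(q / 255, path)
    return(invisible(path))
  }
  if (!ext %in% c("tif", "tiff"))
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  if (type == "float32") {
    write_tiff_float32(pages, path)
  } else {
    bits <- if (type == "uint16") 16L else 8L
    qs <- lapply(pages, quantize, bits = bits)
    maxv <- 2^bits - 1
    out <- lapply(qs, function(q) q / maxv)
    tiff::writeTIFF(if (length(out) == 1L) out[[1L]] else out, path,
                    bits.per.sample = bits)
  }
  invisible(path)
}

# Clip to [0, 2^bits - 1] (warning when pixels are clipped) and round half
# to even, the rounding used by round().
quantize <- function(x, bits) {
  maxv <- 2^bits - 1
  n_clip <- sum(x < 0 | x > maxv)
  if (n_clip > 0)
    warning(sprintf("%d pixel(s) clipped to [0, %d] during %d-bit export",
                    n_clip, maxv, bits), call. = FALSE)
  round(pmin(pmax(x, 0), maxv))
}

#' Run configuration serialization
#'
#' A run configuration bundles the phantom spec, noise parameters, SRF
#' control, optional ROIs, the number of runs and the master seed, and
#' round-trips losslessly through a YAML file.  Per-run seeds are derived
#' as `seed + run_index - 1`, so multi-run averages are reproducible from
#' the file alone.
#'
#' @param noise a [noise_params()] object.
#' @param control an [srf_control()] object.
#' @param phantom optional [phantom_spec()] object.
#' @param runs number of repeated runs (>= 1).
#' @param seed master seed.
#' @param cell,background optional [roi()]s for empirical metrics.
#' @param max_value peak value used for PSNR.
#' @return An object of class `run_config`.
#' @export
run_config <- function(noise = noise_params(), control = srf_control(),
                       phantom = NULL, runs = 1, seed = 1,
                       cell = NULL, background = NULL, max_value = 255) {
  runs <- as.integer(runs)
  if (is.na(runs) || runs < 1L) stop("'runs' must be an integer >= 1", call. = FALSE)
  structure(list(noise = noise, control = control, phantom = phantom,
                 runs = runs, seed = as.integer(seed), cell = cell,
                 background = background, max_value = max_value),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config object")
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  doc <- list(noise = strip(config$noise),
              control = strip(config$control),
              phantom = strip(config$phantom),
              runs = config$runs, seed = config$seed,
              cell = strip(config$cell), background = strip(config$background),
              max_value = config$max_value)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  ctrl <- doc$control
  run_config(
    noise = do.call(noise_params, doc$noise),
    control = srf_control(neighborhood = ctrl$neighborhood, region = ctrl$region,
                          q = ctrl$q, sigma = ctrl$sigma, layers = ctrl$layers,
                          lambda = ctrl$lambda, step = ctrl$step, seed = ctrl$seed),
    phantom = if (!is.null(doc$phantom)) do.call(phantom_spec, doc$phantom),
    runs = doc$runs, seed = doc$seed,
    cell = if (!is.null(doc$cell)) do.call(roi, doc$cell),
    background = if (!is.null(doc$background)) do.call(roi, doc$background),
    max_value = doc$max_value)
}
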