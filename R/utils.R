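# Internal helpers shared across the package.

# Validate a numeric matrix image; returns it with dimnames stripped.
as_image <- function(x, arg = "image", require_finite = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (require_finite && !all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  storage.mode(x) <- "double"
  attributes(x) <- list(dim = dim(x))
  x
}

stopifnot_scalar <- function(x, arg, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric scalar", arg), call. = FALSE)
  invisible(x)
}

# Mirror (symmetric, edge-repeating) index for 0-based coordinates, total for
# any integer offset.  Period-2n folding, so it is defined even when the
# shift exceeds the image size.
mirror_index <- function(i, n) {
  p <- ((i %% (2L * n)) + 2L * n) %% (2L * n)
  ifelse(p < n, p, 2L * n - 1L - p)
}

# Image shifted by (dr, dc) with mirror boundary: result[r, c] = x[r+dr, c+dc].
shift_mirror <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  ri <- mirror_index(seq_len(h) - 1L + dr, h) + 1L
  ci <- mirror_index(seq_len(w) - 1L + dc, w) + 1L
  x[ri, ci, drop = FALSE]
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("'seed' must be a single finite number or NULL", call. = FALSE)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
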