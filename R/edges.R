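#' Control parameters for the SRF denoiser
#'
#' All tunable knobs of the stochastically-connected random field model.
#'
#' @param neighborhood odd integer >= 3, side of the square neighbourhood
#'   within which a pixel may be connected (default 11, the recommended
#'   "fairly large" higher-order neighbourhood).
#' @param region odd integer >= 1, side of the square patch used for the
#'   regional (patch-based) distance between two sites (default 3, the
#'   smallest patch consistent with a point-spread function wider than one
#'   pixel).  Must not exceed `neighborhood`.
#' @param q flexibility constant Q > 0 of the stochastic connectivity law
#'   `P(edge) = exp(-d/Q)`.  Defaults to `sigma` (flexibility tied to the
#'   smoothness scale).
#' @param sigma smoothness constant of the edge weight `exp(-d^2/sigma^2)`,
#'   in variance-stabilized intensity units (default 1, the noise standard
#'   deviation after stabilization).
#' @param layers number of SRF layers, each taking a single gradient step
#'   (default 20).  `layers = 0` reduces the denoiser to a
#'   variance-stabilization round trip.
#' @param lambda regularization weight between the data-fidelity (unary)
#'   and smoothness (pairwise) energies, >= 0 (default 1).
#' @param step gradient-descent step size beta > 0 (default 0.5).
#' @param seed optional integer seed controlling the stochastic edge
#'   sampling; a fixed seed makes the denoiser fully reproducible.
#' @return An object of class `srf_control`.
#' @examples
#' srf_control(sigma = 1.2, layers = 10, seed = 7)
#' @export
srf_control <- function(neighborhood = 11, region = 3, q = NULL, sigma = 1,
                        layers = 20, lambda = 1, step = 0.5, seed = NULL) {
  neighborhood <- as.integer(neighborhood)
  region <- as.integer(region)
  if (is.na(neighborhood) || neighborhood < 3L || neighborhood %% 2L == 0L)
    stop("'neighborhood' must be an odd integer >= 3", call. = FALSE)
  if (is.na(region) || region < 1L || region %% 2L == 0L)
    stop("'region' must be an odd integer >= 1", call. = FALSE)
  if (region > neighborhood)
    stop("'region' must not exceed 'neighborhood'", call. = FALSE)
  stopifnot_scalar(sigma, "sigma")
  if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (is.null(q)) q <- sigma
  stopifnot_scalar(q, "q")
  if (q <= 0) stop("'q' must be > 0", call. = FALSE)
  layers <- as.integer(layers)
  if (is.na(layers) || layers < 0L) stop("'layers' must be an integer >= 0", call. = FALSE)
  stopifnot_scalar(lambda, "lambda")
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  stopifnot_scalar(step, "step")
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  structure(list(neighborhood = neighborhood, region = region,
                 q = as.numeric(q), sigma = as.numeric(sigma),
                 layers = layers, lambda = as.numeric(lambda),
                 step = as.numeric(step),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "srf_control")
}

#' @export
print.srf_control <- function(x, ...) {
  cat("SRF control parameters:\n")
  cat(sprintf("  neighbourhood %dx%d, region %dx%d\n",
              x$neighborhood, x$neighborhood, x$region, x$region))
  cat(sprintf("  Q = %g, sigma = %g, layers = %d, lambda = %g, step = %g\n",
              x$q, x$sigma, x$layers, x$lambda, x$step))
  cat(sprintf("  seed = %s\n", if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

# Canonical enumeration of the unordered neighbourhood offsets: for an n x n
# window, one representative (dr, dc) per unordered pixel pair, with dc
# ascending and dr ascending within dc.  This order also fixes the order in
# which random numbers are consumed during edge sampling, in both engines.
neighborhood_offsets <- function(neighborhood) {
  n2 <- (as.integer(neighborhood) - 1L) %/% 2L
  off <- list()
  for (dc in 0:n2) {
    dr <- if (dc == 0L) seq_len(n2) else (-n2):n2
    off[[length(off) + 1L]] <- cbind(dr, rep.int(dc, length(dr)))
  }
  out <- do.call(rbind, off)
  dimnames(out) <- list(NULL, c("dr", "dc"))
  storage.mode(out) <- "integer"
  out
}

#' Regional (patch-based) distance between two sites
#'
#' The L2 norm of the difference between the `region x region` patches
#' centred at sites `i` and `j` (mirror boundary handling), divided by the
#' patch pixel count so values are comparable across region sizes.  Patch
#' distances characterize local spatial-feature context and are more robust
#' to per-pixel outliers than single-pixel differences.
#'
#' @param state numeric matrix (the current solution / observation).
#' @param i,j integer vectors `c(row, col)` (1-based) of the two sites.
#' @param region odd patch side length.
#' @return Non-negative scalar; 0 when `i == j` or the image is constant.
#' @export
regional_distance <- function(state, i, j, region = 3) {
  state <- as_image(state, "state")
  h <- nrow(state); w <- ncol(state)
  if (any(c(i, j) < 1L) || i[1] > h || j[1] > h || i[2] > w || j[2] > w)
    stop("sites must lie within the image", call. = FALSE)
  r2 <- (as.integer(region) - 1L) %/% 2L
  patch <- function(s) {
    ri <- mirror_index((s[1] - 1L) + (-r2):r2, h) + 1L
    ci <- mirror_index((s[2] - 1L) + (-r2):r2, w) + 1L
    state[ri, ci, drop = FALSE]
  }
  sqrt(sum((patch(i) - patch(j))^2)) / (region * region)
}

# Vectorized regional distance map for one offset: value at (r, c) is the
# patch distance between site (r, c) and site (r + dr, c + dc); `valid`
# marks sites whose partner lies inside the image.  Patch accumulation runs
# dc-outer / dr-inner, mirrored exactly by the compiled engine.
regional_distance_map <- function(state, dr, dc, region) {
  h <- nrow(state); w <- ncol(state)
  r2 <- (as.integer(region) - 1L) %/% 2L
  acc <- matrix(0, h, w)
  for (pc in (-r2):r2) {
    for (pr in (-r2):r2) {
      a <- shift_mirror(state, pr, pc)
      b <- shift_mirror(state, dr + pr, dc + pc)
      acc <- acc + (a - b)^2
    }
  }
  rows_ok <- seq_len(h) + dr >= 1L & seq_len(h) + dr <= h
  cols_ok <- seq_len(w) + dc >= 1L & seq_len(w) + dc <= w
  list(d = sqrt(acc) / (region * region),
       valid = outer(rows_ok, cols_ok, `&`))
}

#' Stochastic edge-connection probability
#'
#' Probability that a smoothness edge exists between two sites at regional
#' distance `d`: `P = exp(-d / Q)`.  Equivalently, the edge is kept when `d`
#' does not exceed a threshold drawn from an exponential distribution with
#' mean `Q`, so connections across abrupt intensity changes survive with
#' small but non-zero probability instead of being hard-thresholded away.
#'
#' @param d non-negative distance (vectorized).
#' @param q flexibility constant Q > 0.
#' @return Probabilities in `[0, 1]`, decreasing in `d`, with `P(0) = 1`.
#' @export
connection_probability <- function(d, q) {
  stopifnot_scalar(q, "q")
  if (q <= 0) stop("'q' must be > 0", call. = FALSE)
  if (any(d < 0)) stop("'d' must be non-negative", call. = FALSE)
  exp(-d / q)
}

new_srf_edges <- function(dim, offsets, present) {
  structure(list(dim = dim, offsets = offsets, present = present),
            class = "srf_edges")
}

#' Sample the stochastic clique (edge) set of an SRF layer
#'
#' For every unordered pair of sites falling within each other's
#' `neighborhood x neighborhood` window, an edge is included independently
#' with probability [connection_probability()] evaluated at the regional
#' patch distance computed from `state`.  Each pair is decided exactly once.
#'
#' @param state numeric matrix from which distances are computed (the
#'   previous layer's solution).
#' @param control an [srf_control()] object.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return An object of class `srf_edges` holding the image dimensions, the
#'   canonical offset list (one row per unordered pair direction) and a
#'   logical `height x width x n_offsets` presence array.
#' @seealso [compute_weights()], [as.data.frame.srf_edges()]
#' @export
sample_edges <- function(state, control = srf_control(), seed = NULL) {
  state <- as_image(state, "state")
  if (!inherits(control, "srf_control")) stop("'control' must be an srf_control object")
  set_seed_if(seed)
  h <- nrow(state); w <- ncol(state)
  off <- neighborhood_offsets(control$neighborhood)
  K <- nrow(off)
  present <- array(FALSE, dim = c(h, w, K))
  for (k in seq_len(K)) {
    dm <- regional_distance_map(state, off[k, 1L], off[k, 2L], control$region)
    p <- connection_probability(dm$d, control$q)
    u <- matrix(runif(h * w), h, w)  # drawn for every site to fix the stream
    present[, , k] <- dm$valid & (u < p)
  }
  new_srf_edges(c(h, w), off, present)
}

#' @export
print.srf_edges <- function(x, ...) {
  cat(sprintf("SRF edge set: %d x %d image, %d offset directions, %d edges\n",
              x$dim[1], x$dim[2], nrow(x$offsets), sum(x$present)))
  invisible(x)
}

#' Edge list of an `srf_edges` object
#'
#' @param x an `srf_edges` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Data frame with 1-based site coordinates `i_row, i_col, j_row,
#'   j_col`, one row per unordered edge.
#' @export
as.data.frame.srf_edges <- function(x, row.names = NULL, optional = FALSE, ...) {
  h <- x$dim[1]; w <- x$dim[2]
  out <- list()
  for (k in seq_len(nrow(x$offsets))) {
    idx <- which(x$present[, , k], arr.ind = TRUE)
    if (nrow(idx)) {
      out[[length(out) + 1L]] <- data.frame(
        i_row = idx[, 1], i_col = idx[, 2],
        j_row = idx[, 1] + x$offsets[k, 1L],
        j_col = idx[, 2] + x$offsets[k, 2L])
    }
  }
  if (!length(out)) {
    return(data.frame(i_row = integer(), i_col = integer(),
                      j_row = integer(), j_col = integer()))
  }
  do.call(rbind, out)
}

new_srf_weights <- function(dim, offsets, w, normalized) {
  structure(list(dim = dim, offsets = offsets, w = w, normalized = normalized),
            class = "srf_weights")
}

#' @export
print.srf_weights <- function(x, ...) {
  cat(sprintf("SRF weight map: %d x %d image, %d edges, %s\n",
              x$dim[1], x$dim[2], sum(x$w > 0),
              if (x$normalized) "degree-normalized" else "raw"))
  invisible(x)
}

#' Smoothness weights on a sampled edge set
#'
#' The raw weight of an edge at regional distance `d` is
#' `exp(-d^2 / sigma^2)`; absent edges have weight 0.  With
#' `normalize = TRUE` (the default) each weight is divided by twice the
#' larger of the two incident raw degree sums,
#' `w'_{ij} = w_{ij} / (2 max(Z_i, Z_j))`, so the weights incident to any
#' site sum to at most 1 (indeed at most 1/2).  This keeps every layer's
#' update a contraction at the default step size (see the package
#' vignette).
#'
#' @param state numeric matrix from which distances are computed.
#' @param edges an `srf_edges` object from [sample_edges()].
#' @param sigma smoothness constant > 0.
#' @param region patch side used for distances (must match the one used to
#'   sample the edges; default 3).
#' @param normalize apply the per-site degree normalization (default TRUE).
#' @return An object of class `srf_weights` with a numeric
#'   `height x width x n_offsets` weight array.
#' @export
compute_weights <- function(state, edges, sigma, region = 3, normalize = TRUE) {
  state <- as_image(state, "state")
  if (!inherits(edges, "srf_edges")) stop("'edges' must be an srf_edges object")
  stopifnot_scalar(sigma, "sigma")
  if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  h <- nrow(state); w <- ncol(state)
  if (!identical(c(h, w), as.integer(edges$dim)) && !all(c(h, w) == edges$dim))
    stop("'state' and 'edges' dimensions differ", call. = FALSE)
  off <- edges$offsets
  K <- nrow(off)
  wt <- array(0, dim = c(h, w, K))
  for (k in seq_len(K)) {
    dm <- regional_distance_map(state, off[k, 1L], off[k, 2L], region)
    raw <- exp(-(dm$d^2) / sigma^2)
    raw[!edges$present[, , k]] <- 0
    wt[, , k] <- raw
  }
  if (normalize) {
    # Incident raw-degree sums: each edge contributes to both endpoints.
    z <- matrix(0, h, w)
    for (k in seq_len(K)) z <- z + wt[, , k]
    for (k in seq_len(K)) {
      dr <- off[k, 1L]; dc <- off[k, 2L]
      ri <- seq_len(h); ci <- seq_len(w)
      rs <- ri[ri + dr >= 1L & ri + dr <= h]
      cs <- ci[ci + dc >= 1L & ci + dc <= w]
      z[rs + dr, cs + dc] <- z[rs + dr, cs + dc] + wt[rs, cs, k]
    }
    for (k in seq_len(K)) {
      dr <- off[k, 1L]; dc <- off[k, 2L]
      wk <- wt[, , k]
      zi <- z
      zj <- shift_mirror(z, dr, dc)  # only used where the pair is valid
      denom <- 2 * pmax(zi, zj)
      wk <- ifelse(wk > 0, wk / denom, 0)
      wt[, , k] <- wk
    }
  }
  new_srf_weights(c(h, w), off, wt, normalize)
}

#' Deterministic baseline weights (standard random field)
#'
#' The non-stochastic weighting schemes the SRF generalizes: `plain` is the
#' full-neighbourhood kernel `exp(-d^2 / sigma^2)`; `hard_threshold`
#' additionally sets weights to zero wherever the regional distance exceeds
#' the connectivity threshold `T`.  Returned weights are raw
#' (unnormalized), for use as comparison baselines.
#'
#' @inheritParams compute_weights
#' @param control an [srf_control()] object (neighbourhood, region, sigma).
#' @param mode `"plain"` or `"hard_threshold"`.
#' @param threshold connectivity threshold `T` (> 0) for
#'   `mode = "hard_threshold"`.
#' @return An `srf_weights` object (raw weights).
#' @export
deterministic_weights <- function(state, control = srf_control(),
                                  mode = c("plain", "hard_threshold"),
                                  threshold = NULL) {
  state <- as_image(state, "state")
  mode <- match.arg(mode)
  if (mode == "hard_threshold") {
    if (is.null(threshold)) stop("'threshold' required for hard_threshold mode")
    stopifnot_scalar(threshold, "threshold", finite = FALSE)
    if (threshold <= 0) stop("'threshold' must be > 0", call. = FALSE)
  }
  h <- nrow(state); w <- ncol(state)
  off <- neighborhood_offsets(control$neighborhood)
  K <- nrow(off)
  wt <- array(0, dim = c(h, w, K))
  for (k in seq_len(K)) {
    dm <- regional_distance_map(state, off[k, 1L], off[k, 2L], control$region)
    raw <- exp(-(dm$d^2) / control$sigma^2)
    raw[!dm$valid] <- 0
    if (mode == "hard_threshold") raw[dm$d > threshold] <- 0
    wt[, , k] <- raw
  }
  new_srf_weights(c(h, w), off, wt, FALSE)
}
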