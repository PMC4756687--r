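#' Unary (data-fidelity) energy
#'
#' Quadratic data-fidelity in the variance-stabilized domain,
#' `sum_i (t_i - t_obs_i)^2` - the energy inside the negative-exponential
#' unary term of the MAP posterior.  After variance stabilization the noise
#' is approximately unit-variance Gaussian, which is what makes the
#' quadratic form appropriate.
#'
#' @param state,observation numeric matrices of equal dimension, both in
#'   the stabilized (VST) domain.
#' @return Non-negative scalar.
#' @export
unary_energy <- function(state, observation) {
  state <- as_image(state, "state"); observation <- as_image(observation, "observation")
  if (!all(dim(state) == dim(observation)))
    stop("'state' and 'observation' dimensions differ", call. = FALSE)
  sum((state - observation)^2)
}

#' Pairwise (smoothness) energy
#'
#' `sum_{(i,j) in edges} w_ij (u_i - u_j)^2` over the unordered edges of a
#' weight map.
#'
#' @param state numeric matrix.
#' @param weights an `srf_weights` object on the same lattice.
#' @return Non-negative scalar.
#' @export
pairwise_energy <- function(state, weights) {
  state <- as_image(state, "state")
  if (!inherits(weights, "srf_weights")) stop("'weights' must be an srf_weights object")
  if (!all(dim(state) == weights$dim))
    stop("'state' and 'weights' dimensions differ", call. = FALSE)
  h <- nrow(state); w <- ncol(state)
  e <- 0
  for (k in seq_len(nrow(weights$offsets))) {
    dr <- weights$offsets[k, 1L]; dc <- weights$offsets[k, 2L]
    rs <- which(seq_len(h) + dr >= 1L & seq_len(h) + dr <= h)
    cs <- which(seq_len(w) + dc >= 1L & seq_len(w) + dc <= w)
    if (!length(rs) || !length(cs)) next
    diff <- state[rs, cs, drop = FALSE] - state[rs + dr, cs + dc, drop = FALSE]
    e <- e + sum(weights$w[rs, cs, k] * diff^2)
  }
  e
}

#' Total MAP energy
#'
#' `unary_energy(state, observation) + lambda * pairwise_energy(state,
#' weights)`: the negative log-posterior (up to constants) whose minimizer
#' is the MAP estimate.
#'
#' @inheritParams unary_energy
#' @inheritParams pairwise_energy
#' @param lambda regularization weight >= 0.
#' @export
total_energy <- function(state, observation, weights, lambda = 1) {
  stopifnot_scalar(lambda, "lambda")
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  unary_energy(state, observation) + lambda * pairwise_energy(state, weights)
}

#' One synchronous gradient-descent step on the total energy
#'
#' Updates every site simultaneously by `state - step * grad E`, with the
#' weights held fixed, where the gradient of [total_energy()] at site `i`
#' is `2 (t_i - t_obs_i) + lambda * sum_{j: (i,j) in edges} 2 w_ij (t_i -
#' t_j)`.
#'
#' @inheritParams total_energy
#' @param step step size > 0.
#' @return Updated state matrix.
#' @export
gradient_step <- function(state, observation, weights, lambda = 1, step = 0.5) {
  stopifnot_scalar(step, "step")
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  state <- as_image(state, "state"); observation <- as_image(observation, "observation")
  if (!inherits(weights, "srf_weights")) stop("'weights' must be an srf_weights object")
  if (!all(dim(state) == dim(observation)) || !all(dim(state) == weights$dim))
    stop("dimension mismatch between state, observation and weights", call. = FALSE)
  h <- nrow(state); w <- ncol(state)
  g <- 2 * (state - observation)
  for (k in seq_len(nrow(weights$offsets))) {
    dr <- weights$offsets[k, 1L]; dc <- weights$offsets[k, 2L]
    rs <- which(seq_len(h) + dr >= 1L & seq_len(h) + dr <= h)
    cs <- which(seq_len(w) + dc >= 1L & seq_len(w) + dc <= w)
    if (!length(rs) || !length(cs)) next
    wk <- weights$w[rs, cs, k]
    diff <- state[rs, cs, drop = FALSE] - state[rs + dr, cs + dc, drop = FALSE]
    contrib <- 2 * lambda * wk * diff
    g[rs, cs] <- g[rs, cs] + contrib
    g[rs + dr, cs + dc] <- g[rs + dr, cs + dc] - contrib
  }
  state - step * g
}
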