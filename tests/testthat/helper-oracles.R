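# Shared fixtures and independent brute-force oracles used across tests.

# Deterministic random texture.
texture <- function(h, w = h, seed = 42, lo = 0, hi = 10) {
  set.seed(seed)
  matrix(runif(h * w, lo, hi), h, w)
}

# Independent patch extraction with symmetric (edge-repeating) mirroring,
# written directly from the definition.
oracle_patch <- function(img, r, c, region) {
  r2 <- (region - 1) / 2
  refl <- function(i, n) {
    while (any(i < 1) || any(i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  img[refl(r + (-r2):r2, nrow(img)), refl(c + (-r2):r2, ncol(img)), drop = FALSE]
}

oracle_regional_distance <- function(img, i, j, region) {
  a <- oracle_patch(img, i[1], i[2], region)
  b <- oracle_patch(img, j[1], j[2], region)
  sqrt(sum((a - b)^2)) / region^2
}

# Energies recomputed by explicit loops over the edge list.
oracle_pairwise_energy <- function(state, weights) {
  tot <- 0
  for (k in seq_len(nrow(weights$offsets))) {
    dr <- weights$offsets[k, 1]; dc <- weights$offsets[k, 2]
    for (r in seq_len(nrow(state))) for (c in seq_len(ncol(state))) {
      jr <- r + dr; jc <- c + dc
      if (jr < 1 || jr > nrow(state) || jc < 1 || jc > ncol(state)) next
      tot <- tot + weights$w[r, c, k] * (state[r, c] - state[jr, jc])^2
    }
  }
  tot
}

oracle_total_energy <- function(state, obs, weights, lambda) {
  sum((state - obs)^2) + lambda * oracle_pairwise_energy(state, weights)
}

# A small complete-neighbourhood weight map with edges forced present.
full_weights <- function(state, neighborhood, region = 3, sigma = 1,
                         normalize = TRUE) {
  edges <- sample_edges(state, srf_control(neighborhood = neighborhood,
                                           region = region, q = 1e9,
                                           sigma = sigma), seed = 1)
  compute_weights(state, edges, sigma, region = region, normalize = normalize)
}

# Shared small phantom with its acquisition parameters.
small_phantom <- function(size = 48, beta = 0.5, seed_truth = 11) {
  sp <- phantom_spec(size = c(size, size), n_profiles = 40, beta = beta)
  set.seed(seed_truth)
  truth <- add_background_profiles(phantom_base(sp, seed = NULL), sp, seed = NULL)
  list(spec = sp, truth = truth,
       noise = noise_params(g0 = 1 / beta, m = sp$dark_mean,
                            sigma_eps = sp$dark_std))
}
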