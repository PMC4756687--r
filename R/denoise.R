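# One SRF layer in pure R, composed from the exported building blocks.
# Consumes random numbers in the same order as the compiled engine.
srf_layer_r <- function(state, obs, control) {
  edges <- sample_edges(state, control, seed = NULL)
  wts <- compute_weights(state, edges, control$sigma, region = control$region)
  e_pre <- total_energy(state, obs, wts, control$lambda)
  new_state <- gradient_step(state, obs, wts, control$lambda, control$step)
  e_post <- total_energy(new_state, obs, wts, control$lambda)
  list(state = new_state, energy_pre = e_pre, energy_post = e_post)
}

#' Denoise a fluorescence-microscopy image with a stochastically-connected
#' random field
#'
#' Fits the SRF maximum a posteriori estimate of the noise-free image.  The
#' observation is first mapped to the variance-stabilized domain
#' ([vst_forward()]), where the Poisson-Gaussian noise is approximately
#' unit-variance Gaussian and the data-fidelity term is quadratic.  Each of
#' the `control$layers` layers then (i) samples a stochastic edge set from
#' the current state ([sample_edges()]), (ii) computes degree-normalized
#' smoothness weights ([compute_weights()]), and (iii) takes one
#' synchronous gradient step ([gradient_step()]) on the layer energy, with
#' the layer's observation set to the state the layer started from (the
#' previous layer's solution).  The final state is mapped back with
#' [vst_inverse()].
#'
#' With `control$layers = 0` the result is just the stabilization round
#' trip, which is the identity on the valid domain of the transform.  Given
#' `control$seed`, the whole procedure is deterministic.
#'
#' @param observed numeric matrix of detector counts (one channel).
#'   Multi-channel images should be denoised per channel, each with its own
#'   smoothness constant (see [run_denoise()]).
#' @param noise a [noise_params()] object describing the acquisition.
#' @param control an [srf_control()] object.  If `control$sigma` is `NULL`
#'   it is estimated as the standard deviation of the stabilized
#'   observation over `background`; `control$q` defaults to
#'   `control$sigma`.
#' @param background optional [roi()] of photon-free background used to
#'   estimate the smoothness constant.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation).  The two consume the same random-number stream and
#'   agree to numerical round-off.
#' @return An object of class `srf_denoise` with components `estimate`
#'   (the denoised image), `observed`, `noise`, `control`, `engine` and
#'   `energy` (a data frame with the total energy before and after each
#'   layer's gradient step).
#' @examples
#' sp <- phantom_spec(size = c(48, 48), n_profiles = 40)
#' truth <- add_background_profiles(phantom_base(sp, seed = 1), sp, seed = 2)
#' noisy <- simulate_acquisition(truth, sp, seed = 3)
#' fit <- srf_denoise(noisy, noise_params(g0 = 1 / sp$beta, m = 12, sigma_eps = 0.5),
#'                    srf_control(layers = 5, seed = 4))
#' isnr_db(truth, noisy, fitted(fit))
#' @export
srf_denoise <- function(observed, noise = noise_params(),
                        control = srf_control(), background = NULL,
                        engine = c("cpp", "r")) {
  observed <- as_image(observed, "observed")
  engine <- match.arg(engine)
  if (!inherits(noise, "noise_params")) stop("'noise' must be a noise_params object")
  if (!inherits(control, "srf_control")) stop("'control' must be an srf_control object")
  if (!is.null(background)) {
    bg <- vst_forward(roi_pixels(observed, background), noise)
    control$sigma <- max(sd(bg), .Machine$double.eps)
    control$q <- control$sigma
  }
  t_state <- vst_forward(observed, noise)
  set_seed_if(control$seed)
  off <- neighborhood_offsets(control$neighborhood)
  energy <- data.frame(layer = integer(0), energy_pre = numeric(0),
                       energy_post = numeric(0))
  if (control$layers > 0L) {
    for (l in seq_len(control$layers)) {
      res <- if (engine == "cpp") {
        .srf_layer_cpp(t_state, t_state, off, control$region,
                       control$q, control$sigma, control$lambda, control$step)
      } else {
        srf_layer_r(t_state, t_state, control)
      }
      t_state <- res$state
      energy <- rbind(energy, data.frame(layer = l,
                                         energy_pre = res$energy_pre,
                                         energy_post = res$energy_post))
    }
  }
  estimate <- vst_inverse(t_state, noise)
  structure(list(estimate = estimate, observed = observed, noise = noise,
                 control = control, engine = engine, energy = energy,
                 call = match.call()),
            class = "srf_denoise")
}
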