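test_that("zero layers reduce the denoiser to the stabilization round trip", {
  img <- texture(10, seed = 20, lo = 1, hi = 200)
  fit <- srf_denoise(img, noise_params(1, 0, 0), srf_control(layers = 0))
  expect_equal(fitted(fit), img, tolerance = 1e-9)
  expect_equal(nrow(fit$energy), 0)
})

test_that("a constant image is a fixed point of the denoiser", {
  cst <- matrix(80, 16, 16)
  fit <- srf_denoise(cst, noise_params(1, 0, 0),
                     srf_control(neighborhood = 5, layers = 6, seed = 2))
  expect_equal(fitted(fit), cst, tolerance = 1e-6)
})

test_that("compiled and reference engines agree and are seed-reproducible", {
  ph <- small_phantom(size = 14)
  noisy <- simulate_acquisition(ph$truth[1:12, 1:12], ph$spec, seed = 5)
  ctl <- srf_control(neighborhood = 5, layers = 3, seed = 31)
  f_cpp <- srf_denoise(noisy, ph$noise, ctl, engine = "cpp")
  f_r <- srf_denoise(noisy, ph$noise, ctl, engine = "r")
  expect_equal(fitted(f_cpp), fitted(f_r), tolerance = 1e-10)
  expect_equal(f_cpp$energy$energy_pre, f_r$energy$energy_pre, tolerance = 1e-10)
  expect_equal(f_cpp$energy$energy_post, f_r$energy$energy_post, tolerance = 1e-10)
  # same seed: bit-identical; different seed: different edges, different output
  f_rep <- srf_denoise(noisy, ph$noise, ctl, engine = "cpp")
  expect_identical(fitted(f_cpp), fitted(f_rep))
  ctl2 <- ctl; ctl2$seed <- 32L
  expect_false(identical(fitted(f_cpp), fitted(srf_denoise(noisy, ph$noise, ctl2))))
})

test_that("near-deterministic connectivity limits carry through the denoiser", {
  ph <- small_phantom(size = 16)
  noisy <- simulate_acquisition(ph$truth, ph$spec, seed = 8)
  # Q tiny: no edges anywhere, every layer has zero gradient
  ctl0 <- srf_control(neighborhood = 5, q = 1e-9, sigma = 1, layers = 4, seed = 3)
  fit0 <- srf_denoise(noisy, ph$noise, ctl0)
  expect_equal(fitted(fit0), noisy, tolerance = 1e-6)
})

test_that("denoising improves fidelity on a noisy phantom", {
  ph <- small_phantom(size = 48)
  ctl <- srf_control(layers = 10, lambda = 0.3, sigma = 0.5)
  isnrs <- sapply(1:3, function(s) {
    noisy <- simulate_acquisition(ph$truth, ph$spec, seed = 400 + s)
    ctl$seed <- 500 + s
    fit <- srf_denoise(noisy, ph$noise, ctl)
    dm <- ph$spec$dark_mean
    isnr_db(ph$truth, noisy - dm, fitted(fit) - dm)
  })
  expect_gt(mean(isnrs), 0)
})

test_that("background ROI drives the automatic smoothness constant", {
  p <- noise_params(1, 12, 0.5)
  img <- degrade(matrix(c(rep(0, 200), rep(150, 200)), 20, 20), p, seed = 4)
  fit <- srf_denoise(img, p, srf_control(neighborhood = 5, layers = 1, seed = 1),
                     background = roi(0, 0, 10, 20))
  expect_equal(fit$control$sigma, sd(vst_forward(img[1:20, 1:10], p)))
  expect_equal(fit$control$q, fit$control$sigma)
})

test_that("fit object methods are coherent", {
  ph <- small_phantom(size = 20)
  noisy <- simulate_acquisition(ph$truth, ph$spec, seed = 6)
  fit <- srf_denoise(noisy, ph$noise,
                     srf_control(neighborhood = 5, layers = 4, seed = 9))
  expect_s3_class(fit, "srf_denoise")
  expect_identical(residuals(fit), noisy - fitted(fit))
  expect_named(coef(fit), c("q", "sigma", "layers", "lambda", "step",
                            "neighborhood", "region"))
  expect_output(print(fit), "SRF denoising fit")
  sm <- summary(fit)
  expect_true(sm$descent)
  expect_output(print(sm), "energy non-increasing")
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(noisy))
  expect_identical(simulate(fit, 1, seed = 5), simulate(fit, 1, seed = 5))
  pdf(NULL)
  expect_no_error(plot(fit))
  dev.off()
})
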