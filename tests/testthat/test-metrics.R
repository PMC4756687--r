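test_that("ground-truth metrics have their closed forms", {
  t2 <- matrix(c(3, 4), 1, 2)
  expect_equal(snr_db(t2, matrix(c(3, 3), 1, 2)), 10 * log10(25), tolerance = 1e-12)
  expect_identical(snr_db(t2, t2), Inf)
  expect_error(snr_db(matrix(0, 2, 2), matrix(1, 2, 2)), "zero")
  truth <- texture(6, seed = 30); noisy <- texture(6, seed = 31)
  expect_equal(isnr_db(truth, noisy, noisy), 0)
  # halving the MSE gains 10 log10(2) dB
  half <- truth + (noisy - truth) / sqrt(2)
  expect_equal(isnr_db(truth, noisy, half), 10 * log10(2), tolerance = 1e-9)
  cst <- matrix(100, 4, 4)
  expect_equal(psnr_db(cst, cst - 255), 0)
  expect_equal(psnr_db(cst, cst + 25.5), 20)
  expect_identical(psnr_db(cst, cst), Inf)
})

test_that("metrics match two-pass brute-force summation", {
  truth <- texture(16, seed = 32, lo = 1, hi = 200)
  est <- truth + texture(16, seed = 33, lo = -5, hi = 5)
  noisy <- truth + texture(16, seed = 34, lo = -20, hi = 20)
  mse <- function(a, b) { s <- 0; for (i in seq_along(a)) s <- s + (a[i] - b[i])^2; s / length(a) }
  ss <- 0; for (i in seq_along(truth)) ss <- ss + truth[i]^2
  expect_equal(snr_db(truth, est), 10 * log10(ss / (mse(truth, est) * length(truth))))
  expect_equal(isnr_db(truth, noisy, est), 10 * log10(mse(noisy, truth) / mse(est, truth)))
  expect_equal(psnr_db(truth, est, 255), 10 * log10(255^2 / mse(truth, est)))
})

test_that("ISNR equals the PSNR difference identically", {
  for (seed in 1:5) {
    truth <- texture(12, seed = 600 + seed, lo = 0, hi = 255)
    noisy <- truth + texture(12, seed = 700 + seed, lo = -9, hi = 9)
    den <- truth + texture(12, seed = 800 + seed, lo = -3, hi = 3)
    expect_equal(isnr_db(truth, noisy, den),
                 psnr_db(truth, den) - psnr_db(truth, noisy), tolerance = 1e-9)
  }
})

test_that("metrics are invariant to joint transposition and detect shifts", {
  truth <- texture(9, seed = 40, lo = 1, hi = 50)
  est <- truth + texture(9, seed = 41, lo = -2, hi = 2)
  expect_equal(snr_db(truth, est), snr_db(t(truth), t(est)))
  expect_equal(psnr_db(truth, est), psnr_db(t(truth), t(est)))
  # adding a constant to a zero-mean-error estimate lowers PSNR
  err <- texture(9, seed = 42, lo = -1, hi = 1)
  err <- err - mean(err)
  expect_lt(psnr_db(truth, truth + err + 3), psnr_db(truth, truth + err))
})

test_that("ROI metrics match hand computation on a planted image", {
  img <- matrix(0, 20, 20)
  set.seed(50)
  img[1:10, 1:10] <- rnorm(100, mean = 0, sd = 2)    # background
  img[11:20, 11:20] <- 40                            # smooth cell region
  cell <- roi(10, 10, 10, 10); bg <- roi(0, 0, 10, 10)
  sb <- sd(img[1:10, 1:10]); mb <- mean(img[1:10, 1:10])
  expect_equal(roi_snr_db(img, cell, bg), 20 * log10(40 / sb))
  expect_equal(roi_cnr_db(img, cell, bg), 20 * log10(abs(40 - mb) / sb))
  # closed forms: unit and hundredfold amplitude ratios
  img2 <- img; img2[11:20, 11:20] <- sb
  expect_equal(roi_snr_db(img2, cell, bg), 0, tolerance = 1e-12)
  img3 <- img; img3[11:20, 11:20] <- mb + 100 * sb
  expect_equal(roi_cnr_db(img3, cell, bg), 40, tolerance = 1e-12)
  # sentinels
  flat <- matrix(5, 20, 20)
  expect_identical(roi_snr_db(flat, cell, bg), Inf)
  expect_identical(roi_cnr_db(img, bg, bg), -Inf)
  expect_error(roi_snr_db(img, roi(15, 15, 10, 10), bg), "outside")
})

test_that("run aggregation averages finite values and counts exclusions", {
  one <- data.frame(metric = "psnr", value_db = 30, run = 1L)
  agg1 <- aggregate_runs(one)
  expect_equal(agg1$mean_db, 30)
  expect_true(is.na(agg1$sd_db))
  two <- rbind(one, data.frame(metric = "psnr", value_db = 10, run = 2L))
  two$value_db <- c(10, 20)
  agg2 <- aggregate_runs(two)
  expect_equal(agg2$mean_db, 15)
  expect_equal(agg2$sd_db, sqrt(50), tolerance = 1e-9)
  set.seed(51)
  vals <- rnorm(30, 25, 2)
  many <- data.frame(metric = "snr", value_db = vals, run = 1:30)
  expect_equal(aggregate_runs(many)$mean_db, sum(vals) / 30)
  withinf <- rbind(many, data.frame(metric = "snr", value_db = Inf, run = 31L))
  agg <- aggregate_runs(withinf)
  expect_equal(agg$n_excluded, 1)
  expect_equal(agg$mean_db, mean(vals))
  expect_error(aggregate_runs(list()), "non-empty")
})

test_that("reports serialize infinities as strings", {
  rep <- data.frame(metric = c("psnr", "psnr", "isnr"),
                    value_db = c(30, Inf, -Inf), run = c(1L, 2L, 1L))
  path <- tempfile(fileext = ".csv")
  write_report(rep, path)
  txt <- readLines(path)
  expect_true(any(grepl("\"inf\"", txt)))
  expect_true(any(grepl("\"-inf\"", txt)))
  expect_true(grepl("dB conventions", txt[1]))
})
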