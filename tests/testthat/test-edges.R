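test_that("regional distance matches direct patch extraction", {
  expect_equal(regional_distance(matrix(5, 8, 8), c(2, 2), c(6, 7)), 0)
  img <- texture(7, seed = 1)
  expect_equal(regional_distance(img, c(3, 4), c(3, 4)), 0)
  # single bright pixel, pair straddling it
  img2 <- matrix(0, 5, 5); img2[3, 3] <- 9
  expect_equal(regional_distance(img2, c(3, 2), c(3, 4), 3),
               oracle_regional_distance(img2, c(3, 2), c(3, 4), 3))
  expect_equal(regional_distance(img2, c(3, 2), c(3, 4), 3), sqrt(2 * 81) / 9)
  # random image, every neighbourhood offset, including border sites
  for (pair in list(list(c(1, 1), c(2, 3)), list(c(7, 7), c(5, 6)),
                    list(c(4, 1), c(4, 3)), list(c(1, 7), c(3, 7)))) {
    expect_equal(regional_distance(img, pair[[1]], pair[[2]], 3),
                 oracle_regional_distance(img, pair[[1]], pair[[2]], 3))
    expect_equal(regional_distance(img, pair[[1]], pair[[2]], 5),
                 oracle_regional_distance(img, pair[[1]], pair[[2]], 5))
  }
  expect_error(regional_distance(img, c(0, 1), c(2, 2)), "within")
})

test_that("connection probability is the exponential law in the distance", {
  expect_equal(connection_probability(0, 2), 1)
  expect_equal(connection_probability(log(2) * 3, 3), 0.5)
  d <- seq(0.1, 10, by = 0.5)
  expect_true(all(diff(connection_probability(d, 1)) < 0))
  expect_error(connection_probability(1, 0), "q")
  expect_error(connection_probability(-1, 1), "non-negative")
})

test_that("edge sampling hits its deterministic limits", {
  img <- texture(10, seed = 2)
  ctl <- function(q) srf_control(neighborhood = 5, q = q, sigma = 1)
  # Q large: complete neighbourhood graph
  e_full <- sample_edges(img, ctl(1e9), seed = 1)
  off <- e_full$offsets
  n_expected <- sum(pmax(10 - abs(off[, 1]), 0) * pmax(10 - abs(off[, 2]), 0))
  expect_equal(sum(e_full$present), n_expected)
  # Q tiny on an image with strictly positive pairwise distances: empty
  e_none <- sample_edges(img, ctl(1e-9), seed = 1)
  expect_equal(sum(e_none$present), 0)
  # constant image: all pairs at distance zero are kept for any Q
  e_const <- sample_edges(matrix(3, 10, 10), ctl(0.37), seed = 1)
  expect_equal(sum(e_const$present), n_expected)
  # deterministic given the seed
  e1 <- sample_edges(img, ctl(1), seed = 9)
  e2 <- sample_edges(img, ctl(1), seed = 9)
  expect_identical(e1$present, e2$present)
})

test_that("empirical edge frequency follows exp(-d/Q)", {
  img <- texture(12, seed = 3)
  ctl <- srf_control(neighborhood = 5, q = 1, sigma = 1)
  k <- 7L
  site <- c(6L, 6L)
  off <- neighborhood_offsets <- sample_edges(img, ctl, seed = 1)$offsets
  d <- regional_distance(img, site, site + off[k, ], ctl$region)
  p <- exp(-d)
  n <- 1500
  set.seed(100)
  hits <- 0L
  for (s in seq_len(n)) {
    e <- sample_edges(img, ctl, seed = NULL)
    hits <- hits + e$present[site[1], site[2], k]
  }
  ci <- 2.576 * sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), ci)
})

test_that("weights match a pair-by-pair brute-force recomputation", {
  img <- texture(4, seed = 4)
  sigma <- 0.8
  w_raw <- full_weights(img, 3, sigma = sigma, normalize = FALSE)
  edf <- as.data.frame(sample_edges(img, srf_control(neighborhood = 3, q = 1e9,
                                                     sigma = sigma), seed = 1))
  # raw weights: exp(-d^2/sigma^2) from the oracle distance
  for (r in seq_len(nrow(edf))) {
    i <- c(edf$i_row[r], edf$i_col[r]); j <- c(edf$j_row[r], edf$j_col[r])
    d <- oracle_regional_distance(img, i, j, 3)
    k <- which(w_raw$offsets[, 1] == j[1] - i[1] & w_raw$offsets[, 2] == j[2] - i[2])
    expect_equal(w_raw$w[i[1], i[2], k], exp(-d^2 / sigma^2))
  }
  # constant image: all raw weights 1 on present edges
  w_const <- full_weights(matrix(2, 4, 4), 3, normalize = FALSE)
  expect_true(all(w_const$w[w_const$w > 0] == 1))
  expect_equal(sum(w_const$w > 0), nrow(edf))
})

test_that("normalized incident weight sums never exceed one half", {
  for (seed in 1:3) {
    img <- texture(9, seed = seed)
    e <- sample_edges(img, srf_control(neighborhood = 5, q = 2, sigma = 1),
                      seed = seed)
    wts <- compute_weights(img, e, sigma = 1, region = 3)
    expect_true(all(wts$w >= 0 & wts$w <= 1))
    s <- matrix(0, 9, 9)
    for (k in seq_len(nrow(wts$offsets))) {
      dr <- wts$offsets[k, 1]; dc <- wts$offsets[k, 2]
      for (r in 1:9) for (c in 1:9) {
        if (wts$w[r, c, k] > 0) {
          s[r, c] <- s[r, c] + wts$w[r, c, k]
          s[r + dr, c + dc] <- s[r + dr, c + dc] + wts$w[r, c, k]
        }
      }
    }
    expect_lte(max(s), 0.5 + 1e-12)
  }
})

test_that("deterministic baselines: plain kernel and hard threshold", {
  img <- texture(6, seed = 5)
  ctl <- srf_control(neighborhood = 5, sigma = 1)
  plain <- deterministic_weights(img, ctl, "plain")
  huge_t <- deterministic_weights(img, ctl, "hard_threshold", threshold = 1e12)
  expect_identical(plain$w, huge_t$w)
  thr <- deterministic_weights(img, ctl, "hard_threshold", threshold = 0.4)
  for (k in seq_len(nrow(thr$offsets))) {
    for (r in 1:6) for (c in 1:6) {
      jr <- r + thr$offsets[k, 1]; jc <- c + thr$offsets[k, 2]
      if (jr < 1 || jr > 6 || jc < 1 || jc > 6) next
      d <- oracle_regional_distance(img, c(r, c), c(jr, jc), 3)
      if (d > 0.4) expect_identical(thr$w[r, c, k], 0)
      else expect_equal(thr$w[r, c, k], exp(-d^2))
    }
  }
  expect_error(deterministic_weights(img, ctl, "hard_threshold"), "threshold")
})

test_that("mean sampled weight equals plain weight times connection probability", {
  img <- texture(8, seed = 6)
  ctl <- srf_control(neighborhood = 5, q = 1, sigma = 1)
  plain <- deterministic_weights(img, ctl, "plain")
  n <- 1200
  set.seed(77)
  acc <- array(0, dim = dim(plain$w))
  for (s in seq_len(n)) {
    e <- sample_edges(img, ctl, seed = NULL)
    w <- compute_weights(img, e, ctl$sigma, region = ctl$region, normalize = FALSE)
    acc <- acc + w$w
  }
  avg <- acc / n
  # expected value of the sampled raw weight is w_plain * P(edge)
  expected <- plain$w
  for (k in seq_len(nrow(plain$offsets))) {
    dm <- srfdenoise:::regional_distance_map(img, plain$offsets[k, 1],
                                             plain$offsets[k, 2], ctl$region)
    expected[, , k] <- expected[, , k] * exp(-dm$d / ctl$q)
  }
  active <- expected > 0.05  # pairs with non-negligible probability mass
  se <- sqrt(expected * (1 - pmin(expected, 1)) / n) + 1e-3
  expect_true(all(abs(avg[active] - expected[active]) < 5 * se[active] + 0.03))
})
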