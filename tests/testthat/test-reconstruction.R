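test_that("average image matches hand values and brute-force summation", {
  const <- array(3.5, c(5, 2, 2))
  expect_equal(average_image(const), matrix(3.5, 2, 2))

  two <- array(c(0, 2), c(2, 1, 1))
  expect_equal(average_image(two)[1, 1], 1)

  mv <- random_movie(50, 4, 6, seed = 11)
  acc <- 0
  for (t in 1:50) acc <- acc + mv[t, , ]
  expect_lt(max(abs(average_image(mv) - acc / 50)), 1e-12)

  expect_error(average_image(mv, c(10, 10)), "frame range")
  expect_error(average_image(mv, c(0, 100)), "frame range")
  # half-open 0-based: [0, 25) is the first 25 frames
  expect_equal(average_image(mv, c(0, 25)),
               average_image(mv[1:25, , , drop = FALSE]))
})

test_that("centered moment images match hand computation and brute force", {
  mv <- random_movie(100, 3, 3, seed = 2)
  expect_equal(moment_image(mv, 1), matrix(0, 3, 3))

  steps <- array(c(0, 0, 1, 1), c(4, 1, 1))
  expect_equal(moment_image(steps, 2)[1, 1], 0.25)
  expect_equal(moment_image(steps, 3)[1, 1], 0)
  expect_equal(moment_image(steps, 4)[1, 1], 0.0625)

  long <- random_movie(1000, 2, 2, seed = 3, rdist = function(n) rgamma(n, 2))
  m4 <- moment_image(long, 4)
  for (i in 1:2) for (j in 1:2)
    expect_lt(rel_err(m4[i, j], brute_moment(long[, i, j], 4)), 1e-10)

  expect_error(moment_image(mv, 0), "order")
  expect_error(moment_image(mv, 2, c(0, 1)), "2 frames")
})

test_that("moment set agrees with per-order moments and Bernoulli theory", {
  mv <- random_movie(200, 4, 3, seed = 4, rdist = function(n) rexp(n))
  ms <- calc_moments(mv, 4)
  expect_length(ms$order_to_image, 4)
  expect_equal(ms$highest_order, 4L)
  expect_equal(ms$average, average_image(mv))
  for (n in 1:4)
    expect_equal(ms$order_to_image[[n]], moment_image(mv, n))

  # variance of a Bernoulli(0.3) pixel: rho (1 - rho) = 0.21, within 3 SE
  set.seed(5)
  bern <- array(rbinom(1e5, 1, 0.3), c(1e5, 1, 1))
  se <- sqrt((0.21 * ((0.7)^3 + 0.3^3) - 0.21^2) / 1e5)
  expect_lt(abs(calc_moments(bern, 2)$order_to_image[[2]][1, 1] - 0.21), 3 * se)
})

test_that("moment-to-cumulant recursion collapses for centered input and matches hand values", {
  mv <- random_movie(500, 3, 4, seed = 6, rdist = function(n) rgamma(n, 1.5))
  ms <- calc_moments(mv, 4)
  ks <- cumulants_from_moments(ms)
  # G_1 = 0 makes the 2nd and 3rd cumulants equal the moments exactly
  expect_identical(ks$order_to_image[[2]], ms$order_to_image[[2]])
  expect_identical(ks$order_to_image[[3]], ms$order_to_image[[3]])

  steps <- array(c(0, 0, 1, 1), c(4, 1, 1))
  k <- cumulants_from_moments(calc_moments(steps, 4))
  expect_equal(k$order_to_image[[4]][1, 1], -0.125)  # 0.0625 - 3 * 0.25^2

  broken <- calc_moments(mv, 4)
  broken$order_to_image[3] <- list(NULL)  # drop order 3
  expect_error(cumulants_from_moments(broken), "order 3")
})

test_that("recursion agrees with the set-partition expansion oracle up to order 8", {
  dists <- list(function(n) rgamma(n, 2),
                function(n) rbinom(n, 1, 0.3) * 5,
                function(n) exp(rnorm(n) / 2))
  for (s in seq_along(dists)) {
    mv <- random_movie(400, 3, 3, seed = 20 + s, rdist = dists[[s]])
    ms <- calc_moments(mv, 8)
    ks <- cumulants_from_moments(ms)
    for (i in 1:3) for (j in 1:3) {
      m_px <- vapply(1:8, function(n) ms$order_to_image[[n]][i, j], numeric(1))
      k_oracle <- bell_cumulants(m_px)
      k_px <- vapply(1:8, function(n) ks$order_to_image[[n]][i, j], numeric(1))
      expect_lt(max(rel_err(k_px[2:8], k_oracle[2:8])), 1e-9)
    }
  }
})

test_that("moments_from_cumulants inverts the recursion", {
  mv <- random_movie(300, 2, 3, seed = 7, rdist = function(n) rexp(n, 0.5))
  ms <- calc_moments(mv, 8)
  back <- moments_from_cumulants(cumulants_from_moments(ms))
  expect_equal(back$order_to_image[[1]], ms$order_to_image[[1]])
  for (n in 2:8)
    expect_lt(max(rel_err(back$order_to_image[[n]], ms$order_to_image[[n]])), 1e-10)

  zeros <- structure(list(order_to_image = rep(list(matrix(0, 2, 2)), 5),
                          highest_order = 5L), class = "sofi_cumulants")
  expect_equal(moments_from_cumulants(zeros)$order_to_image[[4]], matrix(0, 2, 2))

  # Gaussian: only the 2nd cumulant nonzero -> 4th moment is 3 sigma^4
  gauss <- structure(list(order_to_image = c(list(matrix(0, 1, 1), matrix(1, 1, 1)),
                                             rep(list(matrix(0, 1, 1)), 2)),
                          highest_order = 4L), class = "sofi_cumulants")
  expect_equal(moments_from_cumulants(gauss)$order_to_image[[4]][1, 1], 3)
})

test_that("total signal sums every pixel of every frame", {
  const <- array(2, c(6, 4, 4))
  expect_equal(total_signal(const), rep(32, 6))
  single <- array(c(1, 4, 9), c(3, 1, 1))
  expect_equal(total_signal(single), c(1, 4, 9))
  mv <- random_movie(20, 5, 7, seed = 8)
  expect_equal(total_signal(mv), vapply(1:20, function(t) sum(mv[t, , ]), numeric(1)))
})

test_that("monotone smoothing yields a non-increasing bleaching profile", {
  lin <- seq(100, 1, length.out = 50)
  expect_equal(smooth_monotone(lin, 1), lin)

  set.seed(9)
  noisy <- 1000 * exp(-(0:1999) / 1500) + rnorm(2000, sd = 25)
  sm <- smooth_monotone(noisy, 251)
  expect_true(all(diff(sm) <= 0))
  expect_length(sm, 2000)

  expect_equal(smooth_monotone(rep(7, 30), 5), rep(7, 30))
  expect_error(smooth_monotone(lin, 4), "odd")
  expect_error(smooth_monotone(lin, 51), "length")
})

test_that("bleach blocks split at equal fractional decay", {
  # total decay smaller than fbc: a single block spanning everything
  mild <- seq(100, 99, length.out = 200)
  one <- bleach_blocks(mild, 0.04)
  expect_equal(one$blocks, cbind(start = 0L, end = 200L))

  # geometric decay: boundary at the first index where the curve dips below
  # (1 - fbc) times the start value, found here by direct scan
  geo <- 100 * 0.96^((0:1999) / 1000)
  two <- bleach_blocks(geo, 0.04)
  cut <- which(geo < 100 * 0.96)[1] - 1L   # 0-based
  expect_equal(nrow(two$blocks), 2L)
  expect_equal(unname(two$blocks[1, ]), c(0L, cut))
  expect_equal(unname(two$blocks[2, ]), c(cut, 2000L))

  expect_equal(nrow(bleach_blocks(rep(5, 100), 0.1)$blocks), 1L)
  expect_error(bleach_blocks(geo, 1.2), "fbc")
  expect_error(bleach_blocks(seq(1, 2, length.out = 10), 0.1), "non-increasing")
})

test_that("bleaching correction degenerates to the plain reconstruction for one block", {
  mv <- random_movie(300, 6, 6, seed = 10, rdist = function(n) rpois(n, 50))
  plain <- cumulants_from_moments(calc_moments(mv, 4))
  bc <- correct_bleaching(mv, fbc = 0.9, smooth_kernel = 101, highest_order = 4)
  expect_equal(nrow(bc$schedule$blocks), 1L)
  for (n in 1:4)
    expect_equal(bc$order_to_image[[n]], plain$order_to_image[[n]])
})

test_that("block-averaged cumulants match the single-block result on stationary data", {
  # independent replicate movies of one stationary process: the block-split
  # average and the single-block reconstruction estimate the same cumulant
  mv_a <- random_movie(600, 8, 8, seed = 12)
  mv_b <- random_movie(600, 8, 8, seed = 13)
  halves <- cbind(start = c(0L, 300L), end = c(300L, 600L))
  kb <- rsofi:::cumulants_by_blocks(mv_a, halves, 4)$order_to_image[[4]]
  kf <- cumulants_from_moments(calc_moments(mv_b, 4))$order_to_image[[4]]
  dif <- as.vector(kb - kf)
  # Monte-Carlo agreement: mean pixel difference within 3 SE of zero
  expect_lt(abs(mean(dif)), 3 * sd(dif) / sqrt(length(dif)))
})

test_that("bleaching-corrected high-order reconstruction is finite on a bleaching scene", {
  fld <- semicircle_field(n_emitters = 11, radius = 10, center = c(16, 16),
                          bleach_lifetime = 2000 / log(2))
  sim <- simulate_movie(fld, psf_model(1.5), 2000, c(32, 32), seed = 13)
  bc <- correct_bleaching(sim$movie, fbc = 0.04, smooth_kernel = 251, highest_order = 7)
  expect_length(bc$order_to_image, 7)
  for (n in 1:7) expect_true(all(is.finite(bc$order_to_image[[n]])))
})
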