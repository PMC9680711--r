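test_that("empty fields and always-on emitters render exactly", {
  empty <- emitter_field(matrix(numeric(0), 0, 2))
  s0 <- simulate_movie(empty, psf_model(1.5), 5, c(8, 8), seed = 1)
  expect_equal(s0$movie, array(0, c(5, 8, 8)))

  fld <- emitter_field(matrix(c(6, 6), 1), brightness = 80, on_ratio = 1)
  s1 <- simulate_movie(fld, psf_model(1.2), 10, c(11, 11), seed = 2)
  idx <- matrix(0, 11, 11)
  u <- exp(-((row(idx) - 6)^2 + (col(idx) - 6)^2) / (2 * 1.2^2))
  for (t in c(1, 5, 10))
    expect_equal(s1$movie[t, , ], 80 * u, tolerance = 1e-12)
})

test_that("blinking statistics match the stationary Bernoulli marginal", {
  fld <- emitter_field(matrix(c(5, 5), 1), brightness = 100, on_ratio = 0.5)
  s <- simulate_movie(fld, psf_model(1.5), 1e5, c(9, 9), seed = 3)
  rho_hat <- mean(s$traces)
  # dwell correlation inflates the SE of the on fraction (~3x for a
  # 20-frame cycle at rho = 0.5)
  se <- sqrt(0.25 * 9 / 1e5)
  expect_lt(abs(rho_hat - 0.5), 3 * se)
  # peak-pixel variance: for a binary scaled series the sample variance is
  # eps^2 rho_hat (1 - rho_hat); compare to eps^2/4 at matching precision
  v <- var(s$movie[, 5, 5]) * (1e5 - 1) / 1e5
  expect_lt(abs(v - 2500) / 2500, 0.01)
})

test_that("simulation is reproducible and linear in the emitter field", {
  fld <- semicircle_field(n_emitters = 5, radius = 6, center = c(10, 10))
  a <- simulate_movie(fld, psf_model(1.5), 100, c(20, 20), seed = 7)
  b <- simulate_movie(fld, psf_model(1.5), 100, c(20, 20), seed = 7)
  expect_identical(a$movie, b$movie)

  f1 <- emitter_field(matrix(c(6, 6), 1), brightness = 50, on_ratio = 0.3)
  f2 <- emitter_field(matrix(c(12, 12), 1), brightness = 90, on_ratio = 0.7)
  both <- emitter_field(rbind(c(6, 6), c(12, 12)), brightness = c(50, 90),
                        on_ratio = c(0.3, 0.7))
  tr <- blink_traces(both, 200, seed = 8)
  sum_parts <- simulate_movie(f1, psf_model(1.5), 200, c(18, 18),
                              traces = tr[, 1, drop = FALSE])$movie +
               simulate_movie(f2, psf_model(1.5), 200, c(18, 18),
                              traces = tr[, 2, drop = FALSE])$movie
  joint <- simulate_movie(both, psf_model(1.5), 200, c(18, 18), traces = tr)$movie
  expect_equal(joint, sum_parts, tolerance = 1e-12)
})

test_that("the semicircle scene spaces ratios and positions as designed", {
  fld <- semicircle_field()
  expect_equal(nrow(fld$positions), 51L)
  expect_equal(unique(round(diff(fld$on_ratio), 6)), 0.0196)
  r <- sqrt((fld$positions[, 1] - 44)^2 + (fld$positions[, 2] - 32)^2)
  expect_lt(max(abs(r - 26)), 1e-9)
  # on-time ratio increases left to right across the arc
  expect_true(all(diff(fld$positions[, 2]) > 0))

  two <- semicircle_field(n_emitters = 2, rho_min = 0.2, rho_max = 0.8)
  expect_equal(two$on_ratio, c(0.2, 0.8))
  expect_error(semicircle_field(rho_min = 0.5, rho_max = 0.2), "rho_min")
})

test_that("photobleaching truncates traces with exponential survival", {
  fld <- emitter_field(matrix(c(4, 4), 1), on_ratio = 0.4, bleach_lifetime = Inf)
  unb <- blink_traces(fld, 500, seed = 9)
  ble <- bleach_traces(fld, 500, seed = 9)
  expect_identical(ble$traces, unb)

  many <- emitter_field(cbind(rep(1, 1e4), rep(1, 1e4)), on_ratio = 1,
                        bleach_lifetime = 1)
  bt <- bleach_traces(many, 7, seed = 10)
  for (t in 1:5) {
    surv <- mean(bt$traces[t + 1L, ] == 1)   # frame index t (0-based)
    p <- exp(-t)
    expect_lt(abs(surv - p), 3 * sqrt(p * (1 - p) / 1e4) + 1e-12)
  }

  nofl <- emitter_field(matrix(c(4, 4), 1), on_ratio = 0.4)
  expect_error(bleach_traces(nofl, 10, seed = 1), "bleach_lifetime")
})

test_that("expected total signal decays under bleaching", {
  fld <- semicircle_field(n_emitters = 9, radius = 6, center = c(10, 10),
                          bleach_lifetime = 300)
  acc <- 0
  for (s in 1:100)
    acc <- acc + rowSums(bleach_traces(fld, 600, seed = s)$traces)
  early <- mean(acc[1:100]); late <- mean(acc[501:600])
  expect_lt(late, early * 0.5)   # e^{-500/300} << 0.5 of the initial level
})

test_that("per-pixel time average converges to eps * rho * U", {
  fld <- emitter_field(matrix(c(7, 7), 1), brightness = 60, on_ratio = 0.3)
  s <- simulate_movie(fld, psf_model(1.4), 4e4, c(13, 13), seed = 11)
  ave <- average_image(s$movie)
  rho_hat <- mean(s$traces)             # shared randomness of the one trace
  u <- exp(-((row(ave) - 7)^2 + (col(ave) - 7)^2) / (2 * 1.4^2))
  u[abs(row(ave) - 7) > 6 | abs(col(ave) - 7) > 6] <- 0
  expect_equal(ave, 60 * rho_hat * u, tolerance = 1e-10)
  lam <- 1 - (1 / 6 + 1 / 14)   # telegraph memory: 1 - (1/mean_on + 1/mean_off)
  se <- sqrt(0.3 * 0.7 * (1 + lam) / (1 - lam) / 4e4)
  expect_lt(abs(rho_hat - 0.3), 3 * se)
})
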