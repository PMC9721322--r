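lay1 <- detector_layout(50, 50, 1, 1, edge_width = 0)  # plain 50 x 50 block

test_that("a perfectly planar frame has vanishing local SNR", {
  fr <- outer(1:50, 1:50, function(r, c) 0.5 * r + 0.2 * c + 100)
  s <- local_background_snr(fr, window_spec(), fit_config())
  expect_true(all(is.finite(s)))
  expect_lt(max(abs(s)), 1e-6)
})

test_that("a spiked pixel scores its spike; neighbours are untouched", {
  set.seed(8)
  base <- outer(1:50, 1:50, function(r, c) 0.5 * r + 0.2 * c + 100)
  fr0 <- base + matrix(rnorm(2500, 0, 2), 50, 50)
  fr <- fr0
  fr[25, 25] <- base[25, 25] + 20 * 2  # +20 sigma
  s0 <- local_background_snr(fr0, window_spec(), fit_config())
  s <- local_background_snr(fr, window_spec(), fit_config())
  expect_gt(s[25, 25], 18)
  expect_lt(s[25, 25], 22)
  nb <- rbind(c(24, 25), c(26, 25), c(25, 24), c(25, 26))
  expect_lt(max(abs(s[nb] - s0[nb])), 0.5)
})

test_that("local SNR of pure noise is approximately standard normal", {
  set.seed(13)
  for (i in 1:10) {
    fr <- matrix(rnorm(2500, 500, 7), 50, 50)
    s <- local_background_snr(fr, window_spec(), fit_config())
    expect_lt(abs(mean(s)), 0.05)
    expect_lt(abs(sd(s) - 1), 0.15)
  }
})

test_that("windows thinned below min_pixels are not evaluated", {
  fr <- matrix(rnorm(2500, 100, 1), 50, 50)
  fr[1:40, 1:40] <- NaN
  s <- local_background_snr(fr, window_spec(), fit_config())
  expect_true(is.na(s[20, 20]))
  expect_true(is.finite(s[46, 46]))
})

test_that("local SNR is invariant under affine rescaling of the frame", {
  set.seed(17)
  fr <- matrix(rnorm(2500, 500, 7), 50, 50)
  s1 <- local_background_snr(fr, window_spec(), fit_config())
  s2 <- local_background_snr(3.7 * fr + 120, window_spec(), fit_config())
  expect_lt(max(abs(s1 - s2)), 1e-6)
})

test_that("stride approximation stays close to the dense map", {
  set.seed(23)
  fr <- matrix(rnorm(2500, 500, 7), 50, 50)
  fr[30, 30] <- fr[30, 30] + 100
  s1 <- local_background_snr(fr, window_spec(), fit_config())
  s8 <- local_background_snr(fr, window_spec(stride = 5), fit_config())
  expect_gt(s8[30, 30], 10)
  expect_lt(mean(abs(s1 - s8)), 0.5)
})

test_that("flickering and dead pixels are flagged; clean pixels are not", {
  set.seed(29)
  H <- 50; Tn <- 120
  field <- matrix(500, H, H)
  m <- matrix(rnorm(H * H * Tn, 0, 10), H * H, Tn) + 500
  flick <- (25 - 1) * H + 10   # pixel (10, 25)
  on <- runif(Tn) < 0.3
  m[flick, on] <- m[flick, on] + 10 * 10  # +10 sigma, 30% duty
  dead <- (40 - 1) * H + 35
  m[dead, ] <- rnorm(Tn, 0, 3)
  st <- frame_stack(array(m, c(H, H, Tn)))
  f6 <- illuminated_feature_mask(st, lay1, window_spec(), fit_config())
  expect_true(f6$labels[10, 25])
  expect_gt(f6$snr[10, 25], 8)
  expect_true(f6$labels[35, 40])
  expect_lt(f6$snr[35, 40], -8)
  other <- setdiff(seq_len(H * H), c(flick, dead))
  expect_equal(sum(f6$labels[other]), 0)
  # temporal mean SNR of the flicker pixel is near duty * amplitude
  expect_gt(f6$value[10, 25], 1.5)
})

test_that("flag probability grows with flicker amplitude and duty cycle", {
  set.seed(37)
  H <- 40; Tn <- 80
  amps <- c(2, 6, 18)
  duties <- c(0.05, 0.2, 0.6)
  snr_grid <- matrix(0, 3, 3)
  for (i in seq_along(amps)) {
    for (j in seq_along(duties)) {
      m <- matrix(rnorm(H * H * Tn, 0, 10), H * H, Tn) + 500
      px <- (20 - 1) * H + 20
      on <- runif(Tn) < duties[j]
      m[px, on] <- m[px, on] + amps[i] * 10
      st <- frame_stack(array(m, c(H, H, Tn)))
      f6 <- illuminated_feature_mask(
        st, detector_layout(40, 40, 1, 1, edge_width = 0),
        window_spec(), fit_config())
      snr_grid[i, j] <- f6$snr[20, 20]
    }
  }
  # monotone non-decreasing along both axes (tolerating sampling noise)
  expect_true(all(diff(snr_grid[, 3]) > -1))
  expect_true(all(diff(snr_grid[3, ]) > -1))
  expect_gt(snr_grid[3, 3], snr_grid[1, 1])
})

test_that("pixels unevaluable in most frames get the conservative flag", {
  set.seed(41)
  H <- 50; Tn <- 20
  m <- matrix(rnorm(H * H * Tn, 500, 10), H * H, Tn)
  px <- (25 - 1) * H + 25
  m[px, 1:15] <- NaN  # pre-masked in 75% of frames
  st <- frame_stack(array(m, c(H, H, Tn)))
  f6 <- illuminated_feature_mask(st, lay1, window_spec(), fit_config())
  expect_true(f6$not_evaluable[25, 25])
})

test_that("a 20% illumination ramp is absorbed by the plane model", {
  set.seed(43)
  H <- 64
  lay <- detector_layout(32, 32, 2, 2, edge_width = 1)
  grad <- 0.2 * ((seq_len(H) - 1) / (H - 1) - 0.5)
  field <- matrix(500, H, H) * matrix(1 + grad, H, H, byrow = TRUE)
  Tn <- 60
  m <- matrix(rnorm(H * H * Tn, 0, 10), H * H, Tn) + as.vector(field)
  st <- frame_stack(array(m, c(H, H, Tn)))
  f6 <- illuminated_feature_mask(st, lay, window_spec(), fit_config())
  expect_lte(mean(f6$labels, na.rm = TRUE), 1e-4)
})
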