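lay44 <- detector_layout(20, 20, 2, 2, edge_width = 1)  # 40 x 40 module

test_that("identical frames are all retained", {
  st <- make_stack(matrix(100, 20, 20), T = 10,
                   module_id = "t", memory_cell = 0)
  ff <- frame_quality_filter(st)
  expect_identical(ff$retained, 1:10)
})

test_that("frames with shifted common mode are rejected, others kept", {
  set.seed(11)
  jitter <- rnorm(100, 1000, 1)
  shifted <- c(5L, 17L, 60L)
  jitter[shifted] <- jitter[shifted] + 50
  st <- make_stack(matrix(0, 30, 30), T = 100, noise = 2, jitter = jitter)
  ff <- frame_quality_filter(st)
  expect_identical(setdiff(1:100, ff$retained), shifted)
  # reference: a robust Gaussian over the per-frame robust means flags the
  # same three frames
  g <- fit_gaussian_robust(ff$frame_means)
  expect_identical(which(abs(snr_scores(ff$frame_means, g)) >= 8), shifted)
})

test_that("the frame cap keeps the most typical frames", {
  set.seed(2)
  jitter <- rnorm(512, 0, 1)
  st <- make_stack(matrix(500, 24, 24), T = 512, noise = 3, jitter = jitter)
  ff <- frame_quality_filter(st, max_frames = 200)
  expect_length(ff$retained, 200)
  expect_identical(ff$retained, sort(ff$retained))
  # retained frames have smaller |SNR| than any dropped non-outlier frame
  dropped <- setdiff(which(abs(ff$snr) < 8), ff$retained)
  expect_gte(min(abs(ff$snr[dropped])), max(abs(ff$snr[ff$retained])) - 1e-12)
})

test_that("too few frames or too few survivors abort with a diagnostic", {
  st <- make_stack(matrix(1, 10, 10), T = 5)
  expect_error(frame_quality_filter(st), "at least 10 frames")
})

test_that("exact per-ASIC offset ramps yield no offset flags", {
  offs <- matrix(0, 40, 40)
  for (a in 0:1) for (b in 0:1) {
    ri <- a * 20 + 1:20; ci <- b * 20 + 1:20
    offs[ri, ci] <- outer(1:20, 1:20, function(r, c) 0.01 * r - 0.02 * c +
                            1000 + 10 * a - 5 * b)
  }
  st <- make_stack(offs, T = 20)
  f2 <- offset_feature(st, lay44, config = fit_config(), tile_size = 20)
  expect_equal(sum(f2$labels), 0)
  expect_equal(sum(f2$not_evaluable), 0)
})

test_that("offset outliers are recovered without false positives", {
  set.seed(31)
  offs <- outer(1:40, 1:40, function(r, c) 0.01 * r + 1000) +
    matrix(rnorm(1600, 0, 2), 40, 40)
  edge <- edge_pixels(lay44)
  bad <- sample(which(!edge), 50)
  offs[bad] <- offs[bad] + 30  # 15 population sigma
  st <- make_stack(offs, T = 30, noise = 3)
  f2 <- offset_feature(st, lay44, config = fit_config(), tile_size = 20)
  expect_true(all(f2$labels[bad]))
  # reference: per-tile least squares on clean pixels, same threshold
  expect_equal(sum(f2$labels[setdiff(which(!edge), bad)]), 0)
})

test_that("a constant single-ASIC offset is modelled as a flat plane", {
  lay1 <- detector_layout(32, 32, 1, 1)
  st <- make_stack(matrix(777, 32, 32), T = 10, noise = 1)
  f2 <- offset_feature(st, lay1, config = fit_config())
  pl <- f2$model[[1]]
  expect_lt(abs(pl$intercept + 16 * pl$slope_row + 16 * pl$slope_col - 777),
            0.5)
  expect_equal(sum(f2$labels), 0)
})

test_that("tiles starved by pre-masked pixels are masked conservatively", {
  offs <- matrix(1000, 40, 40)
  st <- make_stack(offs, T = 10, noise = 1)
  x <- unclass(st)
  x[1:20, 1:20, ] <- NaN  # entire first ASIC unusable
  st2 <- frame_stack(x)
  f2 <- offset_feature(st2, lay44, config = fit_config(), tile_size = 20)
  inner <- !edge_pixels(lay44)
  expect_true(all(f2$not_evaluable[1:20, 1:20][inner[1:20, 1:20]]))
  expect_equal(sum(f2$not_evaluable[21:40, 21:40]), 0)
})

test_that("noise feature flags stuck and noisy pixels two-sidedly", {
  set.seed(41)
  offs <- matrix(1000, 40, 40)
  st <- make_stack(offs, T = 60, noise = 3)
  f3 <- noise_feature(st, lay44, config = fit_config())
  expect_equal(sum(f3$labels), 0)  # clean stack: no flags expected

  x <- unclass(st)
  x[10, 10, ] <- 1000          # stuck: zero temporal variance
  x[12, 12, ] <- 1000 + rnorm(60, 0, 30)  # 10x noise
  f3b <- noise_feature(frame_stack(x), lay44, config = fit_config())
  expect_true(f3b$labels[10, 10])
  expect_lt(f3b$snr[10, 10], -8)   # flagged on the low side
  expect_true(f3b$labels[12, 12])
  expect_gt(f3b$snr[12, 12], 8)    # flagged on the high side
})

test_that("dark features are invariant to frame order", {
  set.seed(51)
  offs <- matrix(1000, 40, 40) + matrix(rnorm(1600, 0, 2), 40, 40)
  st <- make_stack(offs, T = 25, noise = 3)
  perm <- sample(25)
  stp <- frame_stack(unclass(st)[, , perm])
  cfg <- fit_config()
  f2a <- offset_feature(st, lay44, config = cfg, tile_size = 20)
  f2b <- offset_feature(stp, lay44, config = cfg, tile_size = 20)
  expect_identical(f2a$value, f2b$value)
  expect_identical(f2a$labels, f2b$labels)
  f3a <- noise_feature(st, lay44, config = cfg)
  f3b <- noise_feature(stp, lay44, config = cfg)
  expect_identical(f3a$value, f3b$value)
  expect_identical(f3a$labels, f3b$labels)
})

test_that("gain separability applies the touching-interval rule", {
  mk <- function(level, s, seed) {
    set.seed(seed)
    make_stack(matrix(level, 40, 40), T = 30, noise = s, kind = "gain",
               seed = seed)
  }
  stacks <- list(high = mk(5000, 10, 1), medium = mk(7000, 10, 2),
                 low = mk(9000, 10, 3))
  f4 <- gain_separability(stacks, lay44, config = fit_config())
  expect_equal(sum(f4$labels), 0)  # gaps >> widths

  # overlapping pair: |100| <= 2 * 300
  stacks2 <- list(high = mk(5000, 300, 4), medium = mk(5100, 300, 5))
  f4b <- gain_separability(stacks2, lay44, config = fit_config())
  inner <- !edge_pixels(lay44)
  expect_true(all(f4b$labels[inner]))

  # symmetric under stage exchange
  f4c <- gain_separability(rev(stacks2), lay44, config = fit_config())
  expect_identical(f4b$labels, f4c$labels)

  expect_error(
    gain_separability(list(high = mk(5000, 10, 1),
                           medium = make_stack(matrix(7000, 10, 10), T = 30,
                                               noise = 10, kind = "gain")),
                      lay44),
    "mismatch")
  expect_error(gain_separability(stacks["high"], lay44), "at least 2")
})

test_that("injected overlapping-level pixels are exactly the masked set", {
  set.seed(61)
  H <- 100
  lay <- detector_layout(50, 50, 2, 2, edge_width = 1)
  base_h <- matrix(5000, H, H)
  base_m <- matrix(7000, H, H)
  inner <- which(!edge_pixels(lay))
  bad <- sample(inner, 100)  # 1% of 10^4
  base_m[bad] <- base_h[bad] + 10  # within one combined sigma (2 x 10)
  stacks <- list(high = make_stack(base_h, T = 40, noise = 10, seed = 62,
                                   kind = "gain"),
                 medium = make_stack(base_m, T = 40, noise = 10, seed = 63,
                                     kind = "gain"))
  f4 <- gain_separability(stacks, lay, config = fit_config())
  flagged <- which(f4$labels)
  expect_setequal(flagged, bad)
})

test_that("gain level outliers are flagged against the pixel population", {
  set.seed(71)
  base <- matrix(6000, 40, 40) + matrix(rnorm(1600, 0, 5), 40, 40)
  edge <- edge_pixels(lay44)
  bad <- sample(which(!edge), 20)
  base[bad] <- base[bad] + 200  # 40 population sigma
  st <- make_stack(base, T = 30, noise = 10, kind = "gain")
  f5 <- gain_level(st, lay44, config = fit_config())
  expect_true(all(f5$labels[bad]))
  expect_equal(sum(f5$labels[setdiff(which(!edge), bad)]), 0)
})

test_that("constant gain indicator with the sigma floor masks nothing", {
  st <- make_stack(matrix(6000, 40, 40), T = 20, kind = "gain")
  f5 <- gain_level(st, lay44, config = fit_config(counting_mode = TRUE))
  expect_equal(sum(f5$labels), 0)
})
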