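small_sim <- function(...) {
  sim_config(layout = detector_layout(24, 24, 2, 2, edge_width = 1),
             T_dark = 50, T_flat = 40, ...)
}

test_that("generation is bit-identical for identical configurations", {
  sim <- small_sim(seed = 9)
  a <- generate_dark_stack(sim, 0, "high")
  b <- generate_dark_stack(sim, 0, "high")
  expect_identical(unclass(a$stack), unclass(b$stack))
  expect_identical(a$truth, b$truth)
  # different context, different realisation
  c2 <- generate_dark_stack(sim, 1, "high")
  expect_false(identical(unclass(a$stack), unclass(c2$stack)))
  fa <- generate_flat_stack(sim, 0)
  fb <- generate_flat_stack(sim, 0)
  expect_identical(unclass(fa$stack), unclass(fb$stack))
})

test_that("defect-free dark stacks reproduce the configured noise scale", {
  rates <- c(hot_offset = 0)
  # frame jitter off so the per-pixel temporal sd is the dark noise alone
  sim <- small_sim(seed = 10, defect_rates = rates, bad_frame_rate = 0,
                   frame_jitter = 0)
  d <- generate_dark_stack(sim, 0, "high")
  expect_equal(nrow(d$truth), 0)
  sds <- robustmask:::temporal_stats(d$stack)$sd
  g <- fit_gaussian_robust(as.vector(sds))
  expect_lt(abs(g$mu_robust - sim$dark_noise) / sim$dark_noise, 0.05)
})

test_that("hot pixels shift the temporal mean by the configured amplitude", {
  sim <- small_sim(seed = 12, defect_rates = c(hot_offset = 0.01),
                   bad_frame_rate = 0)
  d <- generate_dark_stack(sim, 0, "high")
  hot <- truth_idx(d$truth, "hot_offset", sim$layout$H)
  expect_gt(length(hot), 0)
  mu <- robustmask:::temporal_stats(d$stack)$mean
  # reference dark with the same context seed but no defects
  sim0 <- small_sim(seed = 12, defect_rates = c(hot_offset = 0),
                    bad_frame_rate = 0)
  mu0 <- robustmask:::temporal_stats(generate_dark_stack(sim0, 0,
                                                         "high")$stack)$mean
  shift <- (mu[hot] - mu0[hot]) / sim$offset_scatter
  tol <- 3 / sqrt(sim$T_dark) + 3 / sqrt(sim$T_dark)  # mean noise, twice
  expect_true(all(abs(shift - sim$defect_amplitude) <
                    sim$defect_amplitude * 0.3 + tol))
})

test_that("gain stacks separate normal levels and overlap injected ones", {
  sim <- small_sim(seed = 14, defect_rates = c(gain_overlap = 0.01))
  g <- generate_gain_stacks(sim, 0)
  expect_named(g$stacks, c("high", "medium", "low"))
  ov <- truth_idx(g$truth, "gain_overlap", sim$layout$H)
  st <- lapply(g$stacks, robustmask:::temporal_stats)
  gap <- abs(st$high$mean - st$medium$mean)
  width <- st$high$sd + st$medium$sd
  expect_true(all(gap[ov] <= width[ov]))
  normals <- normal_idx(g$truth, sim$layout)
  expect_true(all(gap[normals] > width[normals]))
  # configuration with indistinct normal levels is refused
  expect_error(small_sim(gain_levels = c(high = 5000, medium = 5030)),
               "closer than 3")
})

test_that("flat stacks carry the configured gradient and defects", {
  sim <- small_sim(seed = 16, illum_gradient = 0.2,
                   defect_rates = c(dead_under_light = 0.01),
                   bad_frame_rate = 0)
  fl <- generate_flat_stack(sim, 0)
  mu <- robustmask:::temporal_stats(fl$stack)$mean
  dead <- truth_idx(fl$truth, "dead_under_light", sim$layout$H)
  normals <- normal_idx(fl$truth, sim$layout)
  # left edge ~ 10% below mean level, right edge ~ 10% above
  left <- mean(mu[, 1:4][mu[, 1:4] > 100])
  right <- mean(mu[, 45:48][mu[, 45:48] > 100])
  expect_gt(right - left, 0.12 * sim$flat_level)
  expect_true(all(mu[dead] < 50))
  expect_true(all(mu[normals] > 300))
})

test_that("counting darks are near-zero with stuck pixels standing out", {
  sim0 <- small_sim(seed = 18, counting_mode = TRUE, count_rate = 0,
                    defect_rates = c(stuck = 0))
  d0 <- generate_counting_dark(sim0)
  expect_true(all(unclass(d0$stack) == 0))

  sim <- small_sim(seed = 18, counting_mode = TRUE, count_rate = 1e-3,
                   defect_rates = c(stuck = 0.005))
  d <- generate_counting_dark(sim)
  stuck <- truth_idx(d$truth, "stuck", sim$layout$H)
  m <- robustmask:::stack_matrix(d$stack)
  expect_true(all(m >= 0))
  expect_true(all(m[stuck, ] == sim$count_stuck_value))
  # spurious count rate within a binomial interval
  normals <- normal_idx(d$truth, sim$layout)
  k <- sum(m[normals, ] > 0)
  n <- length(normals) * sim$T_dark
  ci <- qbinom(c(0.0005, 0.9995), n, 1e-3)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  # generate_dark_stack dispatches to counting mode
  d2 <- generate_dark_stack(sim, 0, "single")
  expect_identical(unclass(d2$stack), unclass(d$stack))
})

test_that("configuration guards fire", {
  expect_error(small_sim(defect_rates = c(stuck = 0.2)), "0.05")
  expect_error(small_sim(defect_rates = c(bogus = 0.01)), "unknown")
  expect_error(small_sim(dark_noise = 0), "positive")
  expect_warning(small_sim(defect_amplitude = 4), "not reliably")
})

test_that("truth pixels avoid ASIC edges and classes are disjoint", {
  sim <- small_sim(seed = 20)
  tr <- synthetic_truth(sim)
  lay <- sim$layout
  idx <- (tr$col - 1) * lay$H + tr$row
  expect_equal(anyDuplicated(idx), 0)
  expect_false(any(edge_pixels(lay)[idx]))
  expect_equal(nrow(tr),
               sum(round(sim$defect_rates * sum(!edge_pixels(lay)))))
})
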