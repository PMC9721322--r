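test_that("constant input gives an exact degenerate model", {
  g <- fit_gaussian_robust(c(5, 5, 5, 5))
  expect_identical(g$mu_robust, 5)
  expect_identical(g$sigma_robust, 0)
  g6 <- fit_gaussian_robust(c(5, 5, 5, 5), fit_config(counting_mode = TRUE))
  expect_equal(g6$sigma_robust, 1 / 6)
})

test_that("gross one-sided contamination does not move the fit", {
  set.seed(42)
  x <- c(rnorm(10000, 100, 4), rep(300, 3000))
  g <- fit_gaussian_robust(x)
  # reference: classical moments of the labelled true inliers
  expect_lt(abs(g$mu_robust - mean(x[1:10000])), 0.2)
  expect_lt(abs(g$mu_robust - 100), 0.2)
  expect_gt(g$sigma_robust, 3.6)
  expect_lt(g$sigma_robust, 4.4)
})

test_that("robust fit matches classical moments on clean data", {
  set.seed(7)
  x <- rnorm(10000)
  g <- fit_gaussian_robust(x)
  expect_lt(abs(g$mu_robust - mean(x)), 0.05)
  expect_lt(abs(g$sigma_robust - sd(x)), 0.05)
})

test_that("fit is affine-equivariant", {
  set.seed(11)
  x <- c(rnorm(500, 2, 1.5), rep(60, 100))
  g0 <- fit_gaussian_robust(x)
  for (ab in list(c(2.5, 10), c(-3, 1), c(1e-3, -7), c(-1, 0))) {
    a <- ab[1]; b <- ab[2]
    g <- fit_gaussian_robust(a * x + b)
    mu_ref <- a * g0$mu_robust + b
    expect_lt(abs(g$mu_robust - mu_ref), 1e-9 * max(abs(mu_ref), 1))
    expect_lt(abs(g$sigma_robust - abs(a) * g0$sigma_robust),
              1e-9 * abs(a) * g0$sigma_robust)
  }
})

test_that("classical limit holds over repeated clean draws", {
  set.seed(19)
  n <- 2000
  for (i in 1:20) {
    mu <- runif(1, -50, 50); s <- runif(1, 0.5, 10)
    x <- rnorm(n, mu, s)
    g <- fit_gaussian_robust(x)
    expect_lt(abs(g$mu_robust - mean(x)), 3 * s / sqrt(n))
    expect_lt(abs(g$sigma_robust - sd(x)), 3 * s / sqrt(n))
  }
})

test_that("too few values is an error", {
  expect_error(fit_gaussian_robust(c(1, 2)), "at least 3")
  expect_error(oracle_fit_gaussian(c(1, NA, NA)), "at least 3")
})

test_that("snr_scores is the standardised residual, signed", {
  m <- robustmask:::new_gaussian_model(0, 1, 10)
  expect_equal(snr_scores(c(8.1, -8.1, 7.9), m), c(8.1, -8.1, 7.9))
  expect_equal(snr_scores(0, m), 0)
  m6 <- robustmask:::new_gaussian_model(0, 1 / 6, 10)
  expect_equal(snr_scores(3, m6), 18)
  m0 <- robustmask:::new_gaussian_model(0, 0, 10)
  expect_error(snr_scores(1, m0), "min_scale")
})

test_that("label_outliers thresholds at lambda with the chosen sidedness", {
  m <- robustmask:::new_gaussian_model(0, 1, 10)
  expect_identical(label_outliers(c(7.99, 8.01, -8.01), m, 8),
                   c(FALSE, TRUE, TRUE))
  expect_identical(label_outliers(rep(0, 5), m, 8), rep(FALSE, 5))
  expect_identical(label_outliers(c(9, -9), m, 8, "high_only"),
                   c(TRUE, FALSE))
  expect_identical(label_outliers(c(9, -9), m, 8, "low_only"),
                   c(FALSE, TRUE))
  # P(|Z| >= 8) ~ 1.2e-15: no flags expected among 1000 standard draws
  set.seed(3)
  x <- rnorm(1000)
  g <- fit_gaussian_robust(x)
  expect_equal(sum(label_outliers(x, g, 8)), 0)
})

test_that("outlier sets are monotone in lambda", {
  set.seed(5)
  x <- c(rnorm(500), runif(30, -40, 40))
  g <- fit_gaussian_robust(x)
  for (pair in list(c(2, 4), c(4, 8), c(6, 10))) {
    bad_lo <- label_outliers(x, g, pair[1])
    bad_hi <- label_outliers(x, g, pair[2])
    expect_true(all(bad_lo[bad_hi]))  # high-lambda set contained in low
  }
})

test_that("plane fit recovers exact and contaminated planes", {
  g <- expand.grid(r = 0:14, c = 0:14)
  v <- 2 * g$c + 3 * g$r + 1
  p <- fit_plane_robust(g$r, g$c, v)
  expect_equal(p$slope_row, 3, tolerance = 1e-9)
  expect_equal(p$slope_col, 2, tolerance = 1e-9)
  expect_equal(p$intercept, 1, tolerance = 1e-9)
  expect_equal(p$sigma_robust, 0)

  set.seed(21)
  v2 <- v + rnorm(225, 0, 0.5)
  bad <- sample(225, 67)  # 30% gross outliers
  v2[bad] <- v2[bad] + 100
  p2 <- fit_plane_robust(g$r, g$c, v2)
  # reference: least squares on the uncontaminated points only
  ref <- ls_plane(g$r, g$c, v2, keep = !(seq_len(225) %in% bad))
  expect_lt(abs(p2$slope_row - 3), 0.1)
  expect_lt(abs(p2$slope_col - 2), 0.1)
  expect_lt(abs(p2$slope_row - ref[["r"]]), 0.1)
  expect_lt(abs(p2$slope_col - ref[["c"]]), 0.1)

  p3 <- fit_plane_robust(g$r, g$c, rep(7, 225))
  expect_equal(p3$slope_row, 0, tolerance = 1e-12)
  expect_equal(p3$slope_col, 0, tolerance = 1e-12)
  expect_equal(p3$intercept, 7, tolerance = 1e-12)
})

test_that("degenerate plane inputs are rejected", {
  expect_error(fit_plane_robust(1:5, 1:5, 1:5), "at least 10")
  expect_error(fit_plane_robust(1:20, rep(2, 20), rnorm(20)), "collinear")
})

test_that("reference window-scan fit behaves on canonical cases", {
  o <- oracle_fit_gaussian(c(1, 2, 3, 100))
  expect_equal(o$mu_robust, 2, tolerance = 0.2)
  o2 <- oracle_fit_gaussian(c(-1, 0, 1))
  expect_equal(o2$mu_robust, 0)
})

test_that("main fit agrees with the window-scan reference", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(50:500, 1)
    mu <- runif(1, -100, 100)
    s <- runif(1, 0.5, 20)
    f <- runif(1, 0, 0.4)
    x <- contaminated(n, mu, s, f, shift = 50,
                      two_sided = runif(1) < 0.5)
    g <- fit_gaussian_robust(x)
    o <- oracle_fit_gaussian(x)
    expect_lt(abs(g$mu_robust - o$mu_robust), 0.15 * s)
    expect_lt(abs(g$sigma_robust - o$sigma_robust) / o$sigma_robust, 0.25)
  }
})
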