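#' Robust Gaussian fit to contaminated data
#'
#' Estimates the location and scale of the inlier mode of `values`, assuming
#' at least a `min_fraction_inliers` share of the data is drawn from a single
#' approximately Gaussian mode; the remaining share may lie arbitrarily far
#' away without biasing the estimate.
#'
#' The estimator is median-anchored: absolute residuals from the current
#' centre are sorted and the accepted set grows from the minimum admissible
#' size while the next residual stays within `k_grow` running standard
#' deviations; the pass is repeated with the accepted-set mean as the new
#' centre until it converges.  Because the accepted set is a truncated
#' Gaussian, its standard deviation underestimates the population scale; the
#' truncation point is inferred from the acceptance radius and the
#' truncated-normal variance factor is inverted to correct the bias.  The
#' procedure is fully deterministic.
#'
#' @param values numeric vector; non-finite entries are dropped.  At least 3
#'   finite values are required.
#' @param config a [fit_config()].
#' @return An object of class `gaussian_model` with fields `mu_robust`,
#'   `sigma_robust` (floored at `config$min_scale`) and `n_used`.
#' @examples
#' x <- c(rnorm(1000, 100, 4), rep(300, 200))  # 17% gross contamination
#' fit_gaussian_robust(x)
#' @seealso [snr_scores()], [label_outliers()], [oracle_fit_gaussian()]
#' @export
fit_gaussian_robust <- function(values, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 3)
    stop("robust Gaussian fit needs at least 3 finite values", call. = FALSE)
  f <- cpp_fit_gaussian(v, config$min_fraction_inliers, config$k_grow,
                        config$max_iter)
  new_gaussian_model(
    mu_robust = f$mu,
    sigma_robust = max(f$sigma, config$min_scale),
    n_used = f$n_used,
    n_input = length(v)
  )
}

new_gaussian_model <- function(mu_robust, sigma_robust, n_used,
                               n_input = NA_integer_) {
  structure(
    list(mu_robust = mu_robust, sigma_robust = sigma_robust,
         n_used = as.integer(n_used), n_input = as.integer(n_input)),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<gaussian_model>  mu = %.6g  sigma = %.6g  (n_used = %d/%s)\n",
              x$mu_robust, x$sigma_robust, x$n_used,
              ifelse(is.na(x$n_input), "?", x$n_input)))
  invisible(x)
}

#' Robust plane fit over a pixel window
#'
#' Fits `value ~ slope_row * row + slope_col * col + intercept` to the inlier
#' majority of a set of pixels.  The fit alternates least squares on the
#' current inlier set with a robust Gaussian fit to the residuals of all
#' points; points within `k_plane` robust residual scales of the residual
#' mode are retained for the next pass.  `sigma_robust` is the robust scale
#' of the final inlier residuals, floored at `config$min_scale`.
#'
#' @param rows,cols pixel coordinates (numeric vectors).
#' @param values pixel values; non-finite entries are dropped together with
#'   their coordinates.
#' @param config a [fit_config()].
#' @return An object of class `plane_model` with fields `slope_row`,
#'   `slope_col`, `intercept`, `sigma_robust` and `n_used`.
#' @examples
#' g <- expand.grid(row = 0:14, col = 0:14)
#' v <- 2 * g$col + 3 * g$row + 1
#' fit_plane_robust(g$row, g$col, v)
#' @export
fit_plane_robust <- function(rows, cols, values, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  keep <- is.finite(values) & is.finite(rows) & is.finite(cols)
  rows <- as.numeric(rows[keep])
  cols <- as.numeric(cols[keep])
  values <- as.numeric(values[keep])
  if (length(values) < 10)
    stop("robust plane fit needs at least 10 finite points", call. = FALSE)
  f <- cpp_fit_plane(rows, cols, values, config$min_fraction_inliers,
                     config$k_grow, config$k_plane, config$max_iter)
  if (f$status == 2L)
    stop("plane fit is degenerate: points are collinear in (row, col)",
         call. = FALSE)
  if (f$status != 0L)
    stop("robust plane fit needs at least 10 finite points", call. = FALSE)
  structure(
    list(slope_row = f$slope_row, slope_col = f$slope_col,
         intercept = f$intercept,
         sigma_robust = max(f$sigma, config$min_scale),
         n_used = as.integer(f$n_used)),
    class = "plane_model"
  )
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf(
    "<plane_model>  v = %.6g*row + %.6g*col + %.6g   sigma = %.6g  (n = %d)\n",
    x$slope_row, x$slope_col, x$intercept, x$sigma_robust, x$n_used))
  invisible(x)
}

#' Evaluate a fitted plane at pixel coordinates
#'
#' @param object a `plane_model`.
#' @param rows,cols coordinates at which to evaluate.
#' @param ... unused.
#' @return Numeric vector of plane values.
#' @export
predict.plane_model <- function(object, rows, cols, ...) {
  object$slope_row * as.numeric(rows) + object$slope_col * as.numeric(cols) +
    object$intercept
}

#' Signed SNR of values under a robust Gaussian model
#'
#' `(value - mu_robust) / sigma_robust`, the statistical separability of each
#' value from the inlier model.  The result is signed; thresholding is done
#' by [label_outliers()].
#'
#' @param values numeric vector (non-finite entries give `NA` scores).
#' @param model a `gaussian_model` with `sigma_robust > 0`.
#' @return Numeric vector of SNR scores.
#' @export
snr_scores <- function(values, model) {
  stopifnot(inherits(model, "gaussian_model"))
  if (!is.finite(model$sigma_robust) || model$sigma_robust <= 0)
    stop("model sigma_robust is zero; set a positive `min_scale` ",
         "(1/6 for counting detectors) before scoring", call. = FALSE)
  (as.numeric(values) - model$mu_robust) / model$sigma_robust
}

#' Label outliers by thresholding SNR at lambda
#'
#' A value is an inlier when |SNR| < lambda.  One-sided variants keep only
#' the high or low tail.
#'
#' @param values numeric vector.
#' @param model a `gaussian_model`.
#' @param lambda positive threshold (default 8).
#' @param sidedness which tail(s) count as bad.
#' @return Logical vector: `TRUE` = outlier (bad), `NA` where `values` is
#'   not finite.
#' @examples
#' m <- fit_gaussian_robust(rnorm(1000))
#' label_outliers(c(0, 100), m)
#' @export
label_outliers <- function(values, model, lambda = 8,
                           sidedness = c("two_sided", "high_only",
                                         "low_only")) {
  sidedness <- match.arg(sidedness)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0)
  s <- snr_scores(values, model)
  switch(sidedness,
    two_sided = abs(s) >= lambda,
    high_only = s >= lambda,
    low_only = s <= -lambda
  )
}

#' Brute-force reference fit of the inlier Gaussian
#'
#' Independent reference for [fit_gaussian_robust()], used to validate it on
#' small inputs.  All contiguous windows of the sorted values, of every
#' admissible size (at least `min_fraction_inliers` of the data), are scored
#' by the Gaussian likelihood of the window under its own mean and
#' truncation-corrected standard deviation, plus a uniform-density term for
#' the excluded points; the best-scoring window wins, with ties broken by
#' the smaller window start index.  This is an exhaustive search, O(n^2),
#' intended for n up to a few thousand.
#'
#' @param values numeric vector (>= 3 finite values).
#' @param config a [fit_config()].
#' @return A `gaussian_model`.
#' @export
oracle_fit_gaussian <- function(values, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  x <- sort(as.numeric(values[is.finite(values)]))
  n <- length(x)
  if (n < 3)
    stop("robust Gaussian fit needs at least 3 finite values", call. = FALSE)
  rng <- x[n] - x[1]
  if (rng == 0)
    return(new_gaussian_model(x[1], max(0, config$min_scale), n, n))
  log_out <- -log(rng)  # density of an excluded point
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  m0 <- max(3L, ceiling(config$min_fraction_inliers * n))

  best <- -Inf
  best_mu <- NA_real_
  best_sigma <- NA_real_
  best_m <- NA_integer_
  for (m in m0:n) {
    i <- seq_len(n - m + 1L)
    mu <- (cs[i + m] - cs[i]) / m
    ssq <- (cs2[i + m] - cs2[i]) - m * mu^2
    ssq[ssq < 0] <- 0
    sd_raw <- sqrt(ssq / pmax(m - 1, 1))
    # truncation radius of the window around its own mean
    h <- pmax(x[i + m - 1L] - mu, mu - x[i])
    sigma <- oracle_correct_sigma(sd_raw, h)
    sigma <- pmax(sigma, 1e-12 * (abs(mu) + rng))
    # complete-data likelihood of the inlier/outlier mixture: Gaussian
    # inliers with mixing weight m/n, uniform outliers over the data range
    mix <- m * log(m / n) +
      if (m < n) (n - m) * (log(1 - m / n) + log_out) else 0
    ll <- -m * log(sigma) - 0.5 * ssq / sigma^2 - 0.5 * m * log(2 * pi) +
      mix
    j <- which.max(ll)
    if (ll[j] > best) {
      best <- ll[j]
      best_mu <- mu[j]
      best_sigma <- sigma[j]
      best_m <- m
    }
  }
  new_gaussian_model(best_mu, max(best_sigma, config$min_scale), best_m, n)
}

# invert the truncated-normal sd factor given the truncation radius h:
# with z = h / sigma the window satisfies sd_raw / h = g(z) / z, and
# g(z)/z is strictly decreasing in z, so z is found by bisection
oracle_correct_sigma <- function(sd_raw, h) {
  g <- function(z) {
    q <- 2 * pnorm(z) - 1
    sqrt(pmax(1 - 2 * z * dnorm(z) / pmax(q, 1e-12), 1e-12))
  }
  sigma <- sd_raw
  ok <- sd_raw > 0 & h > 0
  r <- sd_raw[ok] / h[ok]
  lo <- rep(0.2, length(r))
  hi <- rep(8, length(r))
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    up <- g(mid) / mid > r  # ratio too high: truncation point is larger
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  z <- (lo + hi) / 2
  sigma[ok] <- sd_raw[ok] / g(z)
  sigma
}
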