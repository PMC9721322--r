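#' Fitting and thresholding configuration
#'
#' Bundles the parameters shared by every robust fit and outlier decision in
#' the pipeline.  `lambda` is the single global SNR threshold: a pixel (or
#' frame) is an outlier when its |SNR| reaches `lambda`.
#' `min_fraction_inliers` is the smallest share of the input that is assumed
#' to be well-behaved; it bounds the contamination the fits tolerate.
#' `min_scale` floors every fitted scale; photon-counting detectors, whose
#' dark values are almost all zero, use a floor of 1/6 so that a stuck count
#' of `v` has SNR `6 v`.
#'
#' @param lambda positive SNR threshold (default 8).
#' @param min_fraction_inliers assumed inlier share, in [0.5, 1].
#' @param min_scale non-negative floor applied to fitted scales.  Default 0;
#'   forced to 1/6 when `counting_mode = TRUE` and left at its default.
#' @param counting_mode `TRUE` for photon-counting detectors.
#' @param k_grow residual-growth factor of the robust Gaussian fit: the
#'   accepted set grows while the next sorted residual is within `k_grow`
#'   running standard deviations.
#' @param k_plane inlier cut (in robust residual scales) used when refitting
#'   planes; slightly wider than `k_grow` to avoid churn on clean windows.
#' @param max_iter iteration cap for the fixed-point passes.
#' @param f2_sidedness sidedness of the dark-offset labelling; both
#'   abnormally high and abnormally low offsets are defects, so the default
#'   is two-sided.
#' @param k_sep separability multiplier for the gain-indicator interval test.
#'
#' @return An object of class `fit_config`.
#' @examples
#' fit_config()
#' fit_config(counting_mode = TRUE)  # sigma floor 1/6
#' @export
fit_config <- function(lambda = 8,
                       min_fraction_inliers = 0.5,
                       min_scale = NULL,
                       counting_mode = FALSE,
                       k_grow = 3,
                       k_plane = 4,
                       max_iter = 30,
                       f2_sidedness = c("two_sided", "high_only", "low_only"),
                       k_sep = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive number", call. = FALSE)
  if (min_fraction_inliers < 0.5 || min_fraction_inliers > 1)
    stop("`min_fraction_inliers` must lie in [0.5, 1]", call. = FALSE)
  if (is.null(min_scale)) min_scale <- if (counting_mode) 1 / 6 else 0
  if (min_scale < 0) stop("`min_scale` must be >= 0", call. = FALSE)
  structure(
    list(
      lambda = lambda,
      min_fraction_inliers = min_fraction_inliers,
      min_scale = min_scale,
      counting_mode = counting_mode,
      k_grow = k_grow,
      k_plane = k_plane,
      max_iter = as.integer(max_iter),
      f2_sidedness = match.arg(f2_sidedness),
      k_sep = k_sep
    ),
    class = "fit_config"
  )
}

#' @export
print.fit_config <- function(x, ...) {
  cat("<fit_config>\n")
  cat(sprintf("  lambda: %g   min inlier fraction: %g   sigma floor: %g\n",
              x$lambda, x$min_fraction_inliers, x$min_scale))
  cat(sprintf("  mode: %s\n",
              if (x$counting_mode) "photon counting" else "integrating"))
  invisible(x)
}

#' Local-background window specification
#'
#' Windows used by the illuminated-run feature.  The window is a square of
#' side `2 * half_width + 1` pixels; at module borders the window is shifted
#' inward (never shrunk) so it keeps its full area.  `min_pixels` is the
#' smallest number of usable pixels a window may contain (windows thinned
#' below it by pre-masked pixels are not evaluated).  `stride > 1` fits one
#' plane per `stride x stride` block of pixels instead of per pixel, sharing
#' the model inside the block; it is an approximation intended for large
#' modules.
#'
#' @param half_width half the window side, in pixels (default 7, a 15x15
#'   window of 225 pixels).
#' @param min_pixels minimum usable pixels per window (default 200).
#' @param stride model-sharing stride in pixels; 1 (the default) fits a
#'   plane per pixel.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(half_width = 7, min_pixels = 200, stride = 1) {
  half_width <- as.integer(half_width)
  if (half_width < 1) stop("`half_width` must be >= 1", call. = FALSE)
  side <- 2L * half_width + 1L
  if (side * side < min_pixels)
    stop(sprintf("a %dx%d window cannot contain min_pixels = %d pixels",
                 side, side, min_pixels), call. = FALSE)
  structure(
    list(half_width = half_width, min_pixels = as.integer(min_pixels),
         stride = as.integer(stride)),
    class = "window_spec"
  )
}
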