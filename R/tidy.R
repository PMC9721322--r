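#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a robust Gaussian model
#'
#' @param x a `gaussian_model`.
#' @param ... unused.
#' @return A one-row tibble with `mu_robust`, `sigma_robust`, `n_used`,
#'   `n_input`.
#' @export
tidy.gaussian_model <- function(x, ...) {
  tibble::tibble(mu_robust = x$mu_robust, sigma_robust = x$sigma_robust,
                 n_used = x$n_used, n_input = x$n_input)
}

#' @rdname tidy.gaussian_model
#' @export
glance.gaussian_model <- function(x, ...) {
  tibble::tibble(
    mu_robust = x$mu_robust, sigma_robust = x$sigma_robust,
    n_used = x$n_used, n_input = x$n_input,
    inlier_fraction = ifelse(is.na(x$n_input), NA_real_,
                             x$n_used / x$n_input)
  )
}

#' Tidy a robust plane model
#'
#' @param x a `plane_model`.
#' @param ... unused.
#' @return A one-row tibble of the plane coefficients and residual scale.
#' @export
tidy.plane_model <- function(x, ...) {
  tibble::tibble(slope_row = x$slope_row, slope_col = x$slope_col,
                 intercept = x$intercept, sigma_robust = x$sigma_robust,
                 n_used = x$n_used)
}

#' Tidy a feature map into one row per pixel
#'
#' @param x a `feature_map`.
#' @param ... unused.
#' @return A tibble with `row`, `col`, `value`, `snr`, `flagged`,
#'   `not_evaluable`.
#' @export
tidy.feature_map <- function(x, ...) {
  d <- dim(x$value)
  tibble::tibble(
    feature = x$feature_id,
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(x$value),
    snr = as.vector(x$snr),
    flagged = as.vector(x$labels),
    not_evaluable = as.vector(x$not_evaluable)
  )
}

#' Tidy a pixel mask into one row per flagged pixel
#'
#' @param x a `pixel_mask`.
#' @param ... unused.
#' @return A tibble with `row`, `col`, `code` and `flags` (comma-separated
#'   flag names), one row per non-zero pixel.
#' @export
tidy.pixel_mask <- function(x, ...) {
  code <- unclass(x)
  idx <- which(code != 0L, arr.ind = TRUE)
  codes <- code[idx]
  flag_names <- vapply(codes, function(cd) {
    paste(names(mask_bits)[bitwAnd(cd, bitwShiftL(1L, mask_bits)) != 0L],
          collapse = ",")
  }, character(1))
  tibble::tibble(row = idx[, 1], col = idx[, 2], code = codes,
                 flags = flag_names)
}

#' @rdname tidy.pixel_mask
#' @export
glance.pixel_mask <- function(x, ...) {
  s <- summarize_mask(x)
  tibble::tibble(n_pixels = s$n_pixels, n_bad = s$n_bad,
                 fraction_bad = s$fraction_bad)
}

#' Tidy a mask summary (per-bit counts)
#'
#' @param x a `mask_summary`.
#' @param ... unused.
#' @return The `by_bit` tibble.
#' @export
tidy.mask_summary <- function(x, ...) x$by_bit
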