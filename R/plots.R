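#' Plot a pixel mask
#'
#' Raster of the module with bad pixels coloured by their first flagging
#' feature.
#'
#' @param object a `pixel_mask`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pixel_mask <- function(object, ...) {
  code <- unclass(object)
  d <- dim(code)
  first_flag <- function(cd) {
    if (cd == 0L) return("good")
    names(mask_bits)[which(bitwAnd(cd, bitwShiftL(1L, mask_bits)) != 0L)[1]]
  }
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    flag = vapply(as.vector(code), first_flag, character(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$flag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "flag") +
    ggplot2::theme_minimal()
}

#' Plot a feature map
#'
#' Raster of the per-pixel SNR with flagged pixels outlined.
#'
#' @param object a `feature_map`.
#' @param what `"snr"` or `"value"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.feature_map <- function(object, what = c("snr", "value"), ...) {
  what <- match.arg(what)
  df <- tidy.feature_map(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[what]])) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("feature %s", object$feature_id),
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
  flagged <- df[!is.na(df$flagged) & df$flagged, ]
  if (nrow(flagged))
    p <- p + ggplot2::geom_point(data = flagged, colour = "red",
                                 shape = 0, size = 1.2)
  p
}

#' Per-bit bar chart of a mask summary
#'
#' @param x a `mask_summary`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_mask_summary <- function(x, ...) {
  stopifnot(inherits(x, "mask_summary"))
  df <- x$by_bit[x$by_bit$count > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flag, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "pixels flagged") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
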