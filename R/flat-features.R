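#' Per-pixel SNR against the local planar background of one frame
#'
#' For every pixel a plane is fitted robustly to the pixel values in the
#' surrounding window (the pixel itself included as a candidate inlier; the
#' robust fit rejects it automatically if deviant), and the pixel's SNR is
#' its residual from the plane in units of the window's robust residual
#' scale.  Windows at the module border are shifted inward so they keep
#' their full area; windows with fewer than `window$min_pixels` usable
#' pixels yield `NA` (pixel not evaluable in this frame).
#'
#' @param frame numeric `H x W` matrix of one illuminated frame.
#' @param window a [window_spec()]; `window$stride > 1` shares one plane per
#'   stride-sized block of pixels (an approximation for large modules).
#' @param config a [fit_config()].
#' @param usable logical `H x W` matrix of pixels eligible for fitting and
#'   scoring (default: all finite pixels).  ASIC-edge pixels are typically
#'   excluded here.
#' @return Numeric `H x W` matrix of SNR values (`NA` = not evaluable).
#' @export
local_background_snr <- function(frame, window = window_spec(),
                                 config = fit_config(), usable = NULL) {
  stopifnot(is.matrix(frame), inherits(window, "window_spec"),
            inherits(config, "fit_config"))
  if (is.null(usable)) usable <- is.finite(frame)
  stopifnot(identical(dim(usable), dim(frame)))
  cpp_local_plane_snr(frame, usable, window$half_width, window$min_pixels,
                      config$min_fraction_inliers, config$k_grow,
                      config$k_plane, config$max_iter, config$min_scale,
                      window$stride)
}

#' Illuminated-run feature: temporal mean of local-background SNR
#'
#' Computes [local_background_snr()] for every retained frame of a
#' near-flat-field run and averages it (non-robustly) over frames; one
#' Gaussian is then fitted robustly over all pixels' mean SNR and two-sided
#' labelling at `lambda` flags pixels that are too bright or too dim too
#' often.  Pixels not evaluable in more than half of the frames are flagged
#' not-evaluable (masked conservatively).
#'
#' The illumination need not be flat: a smooth gradient is absorbed by the
#' local plane model.  Frames are assumed crystal-free.
#'
#' @param stack illuminated-run [frame_stack()] (around 200 frames are
#'   sufficient).
#' @param layout a [detector_layout()]; ASIC-edge pixels are excluded.
#' @param window a [window_spec()].
#' @param config a [fit_config()].
#' @param retained frame indices to use; `NULL` (default) applies
#'   [frame_quality_filter()] first so that burst or dropout frames do not
#'   bias the temporal means.
#' @return A `feature_map` (feature id `"F6"`).
#' @export
illuminated_feature_mask <- function(stack, layout, window = window_spec(),
                                     config = fit_config(), retained = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(retained))
    retained <- frame_quality_filter(stack, config)$retained
  edge <- edge_pixels(layout)
  d <- dim(stack)
  acc <- matrix(0, d[1], d[2])
  nev <- matrix(0L, d[1], d[2])
  for (t in retained) {
    fr <- stack[, , t]
    # edge pixels stay candidates in the window fits (the robust fit rejects
    # them if deviant) but are excluded from labelling below
    s <- local_background_snr(fr, window, config)
    ok <- is.finite(s)
    acc[ok] <- acc[ok] + s[ok]
    nev <- nev + ok
  }
  Tn <- length(retained)
  value <- acc / pmax(nev, 1)
  value[nev == 0] <- NA_real_
  evaluable <- nev > Tn / 2
  usable <- evaluable & !edge & is.finite(value)
  fm <- population_feature("F6", value, usable, config)
  fm$not_evaluable <- (!evaluable | fm$not_evaluable) & !edge
  fm
}
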