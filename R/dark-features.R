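#' Feature map container
#'
#' One scalar feature value per pixel plus its SNR under the robustly fitted
#' population model, the outlier labels, and a not-evaluable indicator for
#' pixels the feature could not assess (pre-masked, too few frames, or an
#' unanalysable tile).
#'
#' @keywords internal
new_feature_map <- function(feature_id, value, snr, labels, not_evaluable,
                            model = NULL) {
  structure(
    list(feature_id = feature_id, value = value, snr = snr, labels = labels,
         not_evaluable = not_evaluable, model = model),
    class = "feature_map"
  )
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map %s>  %d x %d pixels, %d flagged, %d not evaluable\n",
              x$feature_id, nrow(x$value), ncol(x$value),
              sum(x$labels, na.rm = TRUE), sum(x$not_evaluable)))
  invisible(x)
}

#' Reject frames with abnormal overall intensity
#'
#' The per-frame feature is the robust mean of all pixels in the frame.  A
#' Gaussian is fitted robustly over the per-frame means and frames whose
#' |SNR| reaches `lambda` are dropped.  With `max_frames` set, the retained
#' set is further reduced to the `max_frames` most typical frames (smallest
#' |SNR|); facility dark runs of 512 frames are commonly reduced to 200 this
#' way.
#'
#' @param stack a [frame_stack()] with at least 10 frames.
#' @param config a [fit_config()].
#' @param max_frames optional cap on the number of retained frames.
#' @return An object of class `frame_filter`: `retained` (indices in
#'   original order), `snr` (per input frame), `frame_means`, `model`.
#' @export
frame_quality_filter <- function(stack, config = fit_config(),
                                 max_frames = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  Tn <- n_frames(stack)
  if (Tn < 10)
    stop("frame quality filtering needs at least 10 frames", call. = FALSE)
  means <- cpp_column_robust_mu(stack_matrix(stack),
                                config$min_fraction_inliers, config$k_grow,
                                config$max_iter)
  model <- fit_gaussian_robust(means, config)
  if (model$sigma_robust <= 0) {
    # identical frames: nothing to reject
    snr <- rep(0, Tn)
  } else {
    snr <- snr_scores(means, model)
  }
  retained <- which(abs(snr) < config$lambda)
  if (length(retained) < 3)
    stop("fewer than 3 frames retained after quality filtering; ",
         "the run is unusable", call. = FALSE)
  if (!is.null(max_frames) && length(retained) > max_frames) {
    ord <- order(abs(snr[retained]), retained)
    retained <- sort(retained[ord[seq_len(max_frames)]])
  }
  structure(
    list(retained = retained, snr = snr, frame_means = means, model = model),
    class = "frame_filter"
  )
}

#' @export
print.frame_filter <- function(x, ...) {
  cat(sprintf("<frame_filter>  %d of %d frames retained\n",
              length(x$retained), length(x$snr)))
  invisible(x)
}

# shared guard for population-level Gaussian features
population_feature <- function(feature_id, value, usable, config,
                               sidedness = "two_sided") {
  not_eval <- !usable | !is.finite(value)
  v <- value[!not_eval]
  model <- fit_gaussian_robust(v, config)
  labels <- matrix(FALSE, nrow(value), ncol(value))
  snr <- matrix(NA_real_, nrow(value), ncol(value))
  if (model$sigma_robust > 0) {
    s <- snr_scores(value[!not_eval], model)
    snr[!not_eval] <- s
    bad <- switch(sidedness,
      two_sided = abs(s) >= config$lambda,
      high_only = s >= config$lambda,
      low_only = s <= -config$lambda
    )
    labels[!not_eval] <- bad
  }
  new_feature_map(feature_id, value, snr, labels, not_eval, model)
}

#' Dark-offset feature (per-pixel temporal mean vs local planar model)
#'
#' The offset of each pixel is its non-robust temporal mean over the
#' retained dark frames.  Offsets vary smoothly within an ASIC, so the
#' module is tiled into ASIC-aligned windows (default 64 x 64, never
#' straddling an ASIC boundary) and a plane is fitted robustly to each
#' tile's offsets; a pixel's SNR is its offset residual from the tile plane
#' in units of the tile's robust residual scale.  Labelling is two-sided by
#' default: both abnormally high and abnormally low offsets are defects.
#'
#' Tiles with fewer than 10 usable pixels cannot be modelled; their pixels
#' are flagged not-evaluable (masked conservatively).
#'
#' @param stack dark-run [frame_stack()].
#' @param layout a [detector_layout()]; ASIC-edge pixels are excluded from
#'   the fits and carry no offset label (they are masked separately).
#' @param retained frame indices from [frame_quality_filter()] (default all
#'   frames).
#' @param config a [fit_config()].
#' @param tile_size maximum tile side in pixels.
#' @return A `feature_map` (feature id `"F2"`); `model` holds the per-tile
#'   `plane_model`s.
#' @export
offset_feature <- function(stack, layout, retained = NULL,
                           config = fit_config(), tile_size = 64) {
  stopifnot(inherits(stack, "frame_stack"), inherits(layout, "detector_layout"))
  st <- temporal_stats(stack, retained)
  offsets <- st$mean
  edge <- edge_pixels(layout)
  usable <- !edge & is.finite(offsets) & st$n_finite >= 1
  H <- nrow(offsets); W <- ncol(offsets)
  snr <- matrix(NA_real_, H, W)
  labels <- matrix(FALSE, H, W)
  not_eval <- !usable & !edge
  planes <- list()
  eps_num <- 1e-9 * max(1, max(abs(offsets[usable]), na.rm = TRUE))

  for (tile in tile_grid(layout, tile_size)) {
    ri <- tile$r0:tile$r1
    ci <- tile$c0:tile$c1
    sub_use <- usable[ri, ci]
    if (sum(sub_use) < 10) {
      # unanalysable tile: mask its (non-edge) pixels conservatively
      ne <- not_eval[ri, ci]
      ne[!edge[ri, ci]] <- TRUE
      not_eval[ri, ci] <- ne
      next
    }
    idx <- which(sub_use, arr.ind = TRUE)
    rows <- ri[idx[, 1]] - 1
    cols <- ci[idx[, 2]] - 1
    vals <- offsets[ri, ci][sub_use]
    pl <- fit_plane_robust(rows, cols, vals, config)
    planes[[length(planes) + 1L]] <- pl
    sig <- max(pl$sigma_robust, config$min_scale, eps_num)
    s <- (vals - predict(pl, rows, cols)) / sig
    tile_snr <- matrix(NA_real_, length(ri), length(ci))
    tile_snr[sub_use] <- s
    snr[ri, ci] <- tile_snr
    bad <- switch(config$f2_sidedness,
      two_sided = abs(s) >= config$lambda,
      high_only = s >= config$lambda,
      low_only = s <= -config$lambda
    )
    tile_bad <- matrix(FALSE, length(ri), length(ci))
    tile_bad[sub_use] <- bad
    labels[ri, ci] <- tile_bad
  }
  new_feature_map("F2", offsets, snr, labels, not_eval, planes)
}

#' Dark-noise feature (per-pixel temporal standard deviation)
#'
#' The feature is each pixel's non-robust temporal standard deviation about
#' its own temporal mean.  One Gaussian is fitted robustly over all pixels'
#' standard deviations of the module (per memory cell and gain stage) and
#' labelling is two-sided, so both abnormally noisy pixels and zero-variance
#' (stuck) pixels are flagged.
#'
#' @inheritParams offset_feature
#' @return A `feature_map` (feature id `"F3"`).
#' @export
noise_feature <- function(stack, layout, retained = NULL,
                          config = fit_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!is.null(retained) && length(retained) < 3)
    stop("noise feature needs at least 3 retained frames", call. = FALSE)
  st <- temporal_stats(stack, retained)
  edge <- edge_pixels(layout)
  usable <- !edge & is.finite(st$sd) & st$n_finite >= 3
  fm <- population_feature("F3", st$sd, usable, config)
  fm$not_evaluable <- fm$not_evaluable & !edge
  fm
}

#' Gain-stage separability (indicator intervals must not overlap)
#'
#' For every pixel and gain stage the temporal mean and standard deviation
#' of the gain-stage indicator are computed over the retained frames.  A
#' pixel is masked when, for any pair of stages, the gap between its mean
#' indicator values is within `k_sep` times the sum of the two standard
#' deviations: such a pixel does not present distinguishable values for all
#' of its gain stages.
#'
#' @param stacks named list of gain-indicator [frame_stack()]s, one per gain
#'   stage (at least two), identical pixel shape.
#' @param layout a [detector_layout()].
#' @param retained optional list (same names) of retained frame indices.
#' @param config a [fit_config()]; `config$k_sep` scales the interval test.
#' @return A `feature_map` (feature id `"F4"`); `value` is the smallest
#'   normalised stage gap per pixel, `labels` flags overlapping stages.
#' @export
gain_separability <- function(stacks, layout, retained = NULL,
                              config = fit_config()) {
  if (length(stacks) < 2)
    stop("gain separability needs at least 2 gain stages", call. = FALSE)
  dims <- lapply(stacks, function(s) dim(s)[1:2])
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1)
    stop("gain stacks have mismatched pixel shapes", call. = FALSE)
  stats <- lapply(names(stacks), function(nm) {
    temporal_stats(stacks[[nm]], retained[[nm]])
  })
  H <- dims[[1]][1]; W <- dims[[1]][2]
  edge <- edge_pixels(layout)
  # smallest gap-to-width ratio over stage pairs; <= 1 means overlap
  ratio <- matrix(Inf, H, W)
  overlap <- matrix(FALSE, H, W)
  not_eval <- matrix(FALSE, H, W)
  ns <- length(stats)
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      gap <- abs(stats[[a]]$mean - stats[[b]]$mean)
      width <- config$k_sep * (stats[[a]]$sd + stats[[b]]$sd)
      r <- gap / pmax(width, .Machine$double.eps)
      bad <- gap <= width
      na <- !is.finite(r)
      overlap <- overlap | (bad & !na)
      not_eval <- not_eval | na
      r[na] <- Inf
      ratio <- pmin(ratio, r)
    }
  }
  overlap[edge] <- FALSE
  not_eval[edge] <- FALSE
  new_feature_map("F4", ratio, snr = ratio, labels = overlap,
                  not_evaluable = not_eval)
}

#' Gain-indicator level feature (per-stage temporal mean)
#'
#' The feature is each pixel's temporal mean of the gain-stage indicator for
#' one gain stage and memory cell.  One Gaussian is fitted robustly over all
#' pixels of the module and labelling is two-sided.
#'
#' @inheritParams offset_feature
#' @param stack gain-indicator [frame_stack()] for a single stage.
#' @return A `feature_map` (feature id `"F5"`).
#' @export
gain_level <- function(stack, layout, retained = NULL,
                       config = fit_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  st <- temporal_stats(stack, retained)
  edge <- edge_pixels(layout)
  usable <- !edge & is.finite(st$mean) & st$n_finite >= 1
  fm <- population_feature("F5", st$mean, usable, config)
  fm$feature_id <- "F5"
  fm$not_evaluable <- fm$not_evaluable & !edge
  fm
}
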