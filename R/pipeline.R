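#' Build the bad-pixel mask of one detector module
#'
#' Runs the full per-module pipeline over a set of (memory cell, gain stage)
#' contexts: frame quality filtering, the dark features (offset, noise), the
#' gain-indicator features (separability across stages, level per stage)
#' when indicator data are supplied, and the illuminated feature when a
#' flat-field stack is supplied.  Per-context masks carry one bit per
#' flagging feature plus the ASIC-edge and not-evaluable bits; a collapsed
#' any-context mask is also returned.
#'
#' @param contexts list of contexts; each is a
#'   `list(memory_cell =, gain_stage =, dark = <frame_stack or NULL>,
#'   gain = <frame_stack or NULL>, flat = <frame_stack or NULL>)`.
#'   Gain-separability needs at least two stages with `gain` data in the
#'   same memory cell.
#' @param layout a [detector_layout()].
#' @param config a [fit_config()].
#' @param tile_size dark-offset tile size (default 64, ASIC-aligned).
#' @param window a [window_spec()] for the illuminated feature.
#' @param max_frames optional frame cap after quality filtering.
#' @param manual optional logical `H x W` matrix merged verbatim into every
#'   context under the `manual` bit.
#' @param workers number of parallel workers (forked; contexts are
#'   independent per memory cell, so the result does not depend on
#'   `workers`).
#' @return An object of class `module_mask`: `masks` (named list of
#'   per-context `pixel_mask`, names `cell<k>_<stage>`), `collapsed`
#'   (any-context mask), `features` (per-context feature maps), `layout`,
#'   `config`.
#' @export
build_module_mask <- function(contexts, layout, config = fit_config(),
                              tile_size = 64, window = window_spec(),
                              max_frames = NULL, manual = NULL,
                              workers = 1) {
  stopifnot(inherits(layout, "detector_layout"),
            inherits(config, "fit_config"))
  cells <- unique(vapply(contexts, function(x) x$memory_cell, numeric(1)))

  process_cell <- function(cell) {
    ctxs <- Filter(function(x) x$memory_cell == cell, contexts)
    # gain stacks across stages of this cell feed the separability feature
    gain_stacks <- list()
    gain_retained <- list()
    for (x in ctxs) {
      if (!is.null(x$gain)) {
        ff <- frame_quality_filter(x$gain, config, max_frames)
        gain_stacks[[x$gain_stage]] <- x$gain
        gain_retained[[x$gain_stage]] <- ff$retained
      }
    }
    f4 <- NULL
    if (length(gain_stacks) >= 2)
      f4 <- gain_separability(gain_stacks, layout, gain_retained, config)

    masks <- list()
    feats <- list()
    for (x in ctxs) {
      nm <- sprintf("cell%d_%s", x$memory_cell, x$gain_stage)
      contr <- list(edge_mask(layout))
      cf <- list()
      if (!is.null(x$dark)) {
        ff <- frame_quality_filter(x$dark, config, max_frames)
        f2 <- offset_feature(x$dark, layout, ff$retained, config, tile_size)
        f3 <- noise_feature(x$dark, layout, ff$retained, config)
        contr <- c(contr, list(
          list(labels = f2$labels, bit = "offset"),
          list(labels = f3$labels, bit = "noise"),
          list(labels = f2$not_evaluable | f3$not_evaluable,
               bit = "not_evaluable")
        ))
        cf$frame_filter <- ff
        cf$F2 <- f2
        cf$F3 <- f3
      }
      if (!is.null(x$gain)) {
        f5 <- gain_level(x$gain, layout, gain_retained[[x$gain_stage]],
                         config)
        contr <- c(contr, list(
          list(labels = f5$labels, bit = "gain_level"),
          list(labels = f5$not_evaluable, bit = "not_evaluable")
        ))
        cf$F5 <- f5
      }
      if (!is.null(f4)) {
        contr <- c(contr, list(
          list(labels = f4$labels, bit = "gain_separability"),
          list(labels = f4$not_evaluable, bit = "not_evaluable")
        ))
        cf$F4 <- f4
      }
      if (!is.null(x$flat)) {
        f6 <- illuminated_feature_mask(x$flat, layout, window, config)
        contr <- c(contr, list(
          list(labels = f6$labels, bit = "illuminated"),
          list(labels = f6$not_evaluable, bit = "not_evaluable")
        ))
        cf$F6 <- f6
      }
      if (!is.null(manual))
        contr <- c(contr, list(list(labels = manual, bit = "manual")))
      masks[[nm]] <- combine_masks(contr, module_id = layout$module_id,
                                   memory_cell = x$memory_cell,
                                   gain_stage = x$gain_stage)
      feats[[nm]] <- cf
    }
    list(masks = masks, features = feats)
  }

  results <-
    if (workers > 1 && length(cells) > 1 &&
        .Platform$OS.type == "unix") {
      parallel::mclapply(cells, process_cell, mc.cores = workers)
    } else {
      lapply(cells, process_cell)
    }

  masks <- do.call(c, lapply(results, `[[`, "masks"))
  feats <- do.call(c, lapply(results, `[[`, "features"))
  structure(
    list(masks = masks, collapsed = collapse_masks(masks),
         features = feats, layout = layout, config = config),
    class = "module_mask"
  )
}

#' @export
print.module_mask <- function(x, ...) {
  cat(sprintf("<module_mask>  %d context(s): %s\n", length(x$masks),
              paste(names(x$masks), collapse = ", ")))
  s <- summarize_mask(x$collapsed)
  cat(sprintf("  any-context bad pixels: %d of %d (%.4g%%)\n", s$n_bad,
              s$n_pixels, 100 * s$fraction_bad))
  invisible(x)
}
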