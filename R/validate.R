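#' Self-validation: defect recovery on a synthetic module
#'
#' Generates a complete synthetic data set for one detector module — dark
#' runs per gain stage, gain-indicator runs, and a near-flat-field run, per
#' memory cell — runs the full masking pipeline, and scores the resulting
#' any-context mask against the generator's ground truth: per-class recall
#' of the injected defects and the false-positive fraction among normal
#' (non-defect, non-edge) pixels.
#'
#' The illuminated feature uses the block-sharing stride approximation on
#' the full module; when `dense_crop = TRUE` the leading 128-column crop of
#' the first cell's flat run is additionally analysed with dense per-pixel
#' windows, as a fidelity check on the approximation.
#'
#' @param seed integer seed for the synthetic module.
#' @param cells memory-cell indices to simulate (default `0:1`).
#' @param layout a [detector_layout()] (default: 128 x 512 module of 2 x 8
#'   ASICs of 64 x 64).
#' @param T_dark,T_flat frame counts (defaults 300 and 200).
#' @param defect_amplitude injected effect size in population sigmas
#'   (default 12, the design detectability margin at `lambda = 8`).
#' @param config a [fit_config()].
#' @param stride stride of the full-module illuminated feature.
#' @param dense_crop also run the dense illuminated feature on a 128 x 128
#'   crop of the first cell.
#' @return A list: `recall` (named per defect class), `false_positive_rate`,
#'   `n_defects`, `n_normals`, `collapsed` (the any-context `pixel_mask`),
#'   `crop` (dense-crop recall/false-positive rate, or `NULL`).
#' @export
validate_synthetic_recovery <- function(seed, cells = 0:1,
                                        layout = detector_layout(),
                                        T_dark = 300, T_flat = 200,
                                        defect_amplitude = 12,
                                        config = fit_config(),
                                        stride = 8, dense_crop = TRUE) {
  sim <- sim_config(layout = layout, T_dark = T_dark, T_flat = T_flat,
                    defect_amplitude = defect_amplitude, seed = seed)
  truth <- synthetic_truth(sim)
  stages <- names(sim$gain_levels)
  masks <- list()
  crop_res <- NULL
  for (cell in cells) {
    gains <- generate_gain_stacks(sim, cell)$stacks
    flat <- generate_flat_stack(sim, cell, stages[1])$stack
    contexts <- lapply(stages, function(s) {
      list(memory_cell = cell, gain_stage = s,
           dark = generate_dark_stack(sim, cell, s)$stack,
           gain = gains[[s]],
           flat = if (s == stages[1]) flat)
    })
    mm <- build_module_mask(contexts, layout, config,
                            window = window_spec(stride = stride))
    masks <- c(masks, mm$masks)
    if (dense_crop && cell == cells[1] && layout$W >= 128) {
      ncol_crop <- 128L
      crop <- frame_stack(unclass(flat)[, seq_len(ncol_crop), ],
                          memory_cell = cell)
      crop_lay <- detector_layout(layout$asic_height, layout$asic_width,
                                  layout$n_asic_rows,
                                  ncol_crop %/% layout$asic_width,
                                  layout$edge_width)
      f6 <- illuminated_feature_mask(crop, crop_lay, window_spec(), config)
      in_crop <- truth$col <= ncol_crop &
        truth$class %in% c("flicker_bright", "dead_under_light")
      ci <- (truth$col[in_crop] - 1L) * layout$H + truth$row[in_crop]
      cn <- setdiff(which(!edge_pixels(crop_lay)), ci)
      crop_res <- list(recall = mean(f6$labels[ci]),
                       false_positive_rate =
                         mean(f6$labels[cn], na.rm = TRUE),
                       n_defects = length(ci))
    }
    rm(gains, flat, contexts, mm)
    gc(FALSE)
  }
  collapsed <- collapse_masks(masks)
  idx <- (truth$col - 1L) * layout$H + truth$row
  flagged <- unclass(collapsed)[idx] != 0L
  recall <- vapply(split(flagged, truth$class), mean, numeric(1))
  normals <- setdiff(which(!edge_pixels(layout)), idx)
  list(
    recall = recall,
    false_positive_rate = mean(unclass(collapsed)[normals] != 0L),
    n_defects = nrow(truth),
    n_normals = length(normals),
    collapsed = collapsed,
    crop = crop_res
  )
}
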