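#' Read a frame stack from an HDF5 file
#'
#' Datasets of rank 3 are read as `(T, H, W)`; rank-4 datasets are read as
#' `(T, cell, H, W)` and require a `cell` selection.  Values arrive as
#' doubles; non-finite entries are recorded as pre-masked (attribute
#' `n_premasked`) and excluded from all downstream statistics.
#'
#' @param path HDF5 file path.
#' @param dataset dataset path inside the file (e.g. `"data"`).
#' @param cell memory-cell index (0-based) for rank-4 datasets.
#' @param module_id,memory_cell,gain_stage,kind metadata for the returned
#'   [frame_stack()]; `memory_cell` defaults to `cell`.
#' @return A [frame_stack()] of dimension `H x W x T`.
#' @export
read_frame_stack <- function(path, dataset, cell = NULL, module_id = "m0",
                             memory_cell = NULL,
                             gain_stage = "high", kind = "analogue") {
  if (!file.exists(path))
    stop(sprintf("HDF5 file not found: '%s'", path), call. = FALSE)
  d <- cpp_h5_dims(path, dataset)$dims
  if (length(d) == 3L) {
    r <- cpp_h5_read(path, dataset, -1L, 0L)
    arr <- aperm(array(r$data, rev(r$dims)), c(2, 1, 3))  # (H, W, T)
  } else if (length(d) == 4L) {
    if (is.null(cell))
      stop("rank-4 dataset (T, cell, H, W): a `cell` selection is required",
           call. = FALSE)
    r <- cpp_h5_read(path, dataset, 1L, as.integer(cell))
    a <- array(r$data, rev(r$dims))  # (W, H, 1, T)
    arr <- aperm(a[, , 1L, , drop = TRUE], c(2, 1, 3))
  } else {
    stop(sprintf("dataset '%s' has rank %d; expected 3 (T, H, W) or 4 (T, cell, H, W)",
                 dataset, length(d)), call. = FALSE)
  }
  if (is.null(memory_cell)) memory_cell <- if (is.null(cell)) 0L else cell
  st <- frame_stack(arr, module_id = module_id, memory_cell = memory_cell,
                    gain_stage = gain_stage, kind = kind)
  attr(st, "n_premasked") <- sum(!is.finite(arr))
  st
}

#' Write frame stacks to an HDF5 file
#'
#' A single stack is written as a rank-3 `(T, H, W)` dataset; a list of
#' stacks (one per memory cell) as rank-4 `(T, cell, H, W)`.  The element
#' order on disk follows the C convention of facility files (readable with
#' h5py as written).
#'
#' @param path HDF5 file path (created or truncated unless `append = TRUE`).
#' @param dataset dataset path inside the file.
#' @param stack a [frame_stack()] or list of them (one per cell).
#' @param append keep other datasets already in the file.
#' @export
write_frame_stack <- function(path, dataset, stack, append = FALSE) {
  if (!append || !file.exists(path)) cpp_h5_create(path)
  if (inherits(stack, "frame_stack")) {
    d <- dim(stack)
    cpp_h5_write(path, dataset, as.numeric(aperm(unclass(stack), c(2, 1, 3))),
                 c(d[3], d[1], d[2]), "double")
  } else {
    stopifnot(is.list(stack), length(stack) >= 1)
    d <- dim(stack[[1]])
    nc <- length(stack)
    a <- array(0, c(d[2], d[1], nc, d[3]))
    for (k in seq_len(nc)) {
      stopifnot(identical(dim(stack[[k]]), d))
      a[, , k, ] <- aperm(unclass(stack[[k]]), c(2, 1, 3))
    }
    cpp_h5_write(path, dataset, as.numeric(a), c(d[3], nc, d[1], d[2]),
                 "double")
  }
  invisible(path)
}

#' Write pixel masks to an HDF5 file
#'
#' One unsigned 8-bit dataset per (memory cell, gain stage) context under
#' `masks/`, a collapsed any-context dataset `mask_any`, and root attributes
#' carrying the threshold `lambda`, the sigma floor, the bit legend (JSON)
#' and the full configuration echo (YAML), sufficient to reproduce the mask.
#' Content is deterministic given identical inputs.
#'
#' @param path output HDF5 file path.
#' @param masks named list of `pixel_mask` objects, or a `module_mask`.
#' @param layout the [detector_layout()] used.
#' @param config the [fit_config()] used.
#' @param extra named list of additional scalar attributes (e.g. `seed`).
#' @export
write_mask <- function(path, masks, layout = NULL, config = fit_config(),
                       extra = list()) {
  if (inherits(masks, "module_mask")) {
    layout <- masks$layout
    config <- masks$config
    obj <- masks
    masks <- obj$masks
    collapsed <- obj$collapsed
  } else {
    collapsed <- collapse_masks(masks)
  }
  cpp_h5_create(path)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    ds <- paste0("masks/", nm)
    cpp_h5_write(path, ds, as.integer(t(unclass(m))), dim(m), "uint8")
    if (!is.na(attr(m, "memory_cell")))
      cpp_h5_write_attr(path, ds, "memory_cell",
                        as.numeric(attr(m, "memory_cell")))
    if (!is.na(attr(m, "gain_stage")))
      cpp_h5_write_attr(path, ds, "gain_stage", attr(m, "gain_stage"))
  }
  cpp_h5_write(path, "mask_any", as.integer(t(unclass(collapsed))),
               dim(collapsed), "uint8")
  cpp_h5_write_attr(path, "/", "lambda", config$lambda)
  cpp_h5_write_attr(path, "/", "min_scale", config$min_scale)
  cpp_h5_write_attr(path, "/", "counting_mode",
                    as.numeric(config$counting_mode))
  cpp_h5_write_attr(path, "/", "bit_legend",
                    as.character(jsonlite::toJSON(as.list(mask_bits),
                                                  auto_unbox = TRUE)))
  echo <- list(config = config[c("lambda", "min_fraction_inliers",
                                 "min_scale", "counting_mode", "k_grow",
                                 "k_plane", "f2_sidedness", "k_sep")])
  if (!is.null(layout))
    echo$layout <- layout[c("asic_height", "asic_width", "n_asic_rows",
                            "n_asic_cols", "edge_width", "module_id")]
  cpp_h5_write_attr(path, "/", "config_echo", yaml::as.yaml(echo))
  cpp_h5_write_attr(path, "/", "package_version",
                    as.character(utils::packageVersion("robustmask")))
  for (nm in names(extra)) cpp_h5_write_attr(path, "/", nm, extra[[nm]])
  invisible(path)
}

#' Read pixel masks back from an HDF5 mask file
#'
#' @param path HDF5 file written by [write_mask()].
#' @return A list: `masks` (named list of `pixel_mask`), `mask_any`,
#'   `lambda`, `legend`, `config_echo` (parsed YAML).
#' @export
read_mask <- function(path) {
  names <- if (cpp_h5_exists(path, "masks")) cpp_h5_ls(path, "masks")
           else character(0)
  read_one <- function(ds) {
    r <- cpp_h5_read(path, ds, -1L, 0L)
    cell <- tryCatch(as.integer(cpp_h5_read_attr(path, ds, "memory_cell")),
                     error = function(e) NA_integer_)
    stage <- tryCatch(cpp_h5_read_attr(path, ds, "gain_stage"),
                      error = function(e) NA_character_)
    new_pixel_mask(t(matrix(as.integer(r$data), r$dims[2], r$dims[1])),
                   memory_cell = cell, gain_stage = stage)
  }
  masks <- lapply(names, function(nm) read_one(paste0("masks/", nm)))
  names(masks) <- names
  list(
    masks = masks,
    mask_any = read_one("mask_any"),
    lambda = as.numeric(cpp_h5_read_attr(path, "/", "lambda")),
    legend = jsonlite::fromJSON(cpp_h5_read_attr(path, "/", "bit_legend")),
    config_echo = yaml::yaml.load(cpp_h5_read_attr(path, "/", "config_echo"))
  )
}
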