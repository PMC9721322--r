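#' Detector module layout
#'
#' Describes the ASIC tiling of one detector module: a grid of
#' `n_asic_rows x n_asic_cols` tiles, each `asic_height x asic_width`
#' pixels.  ASIC border pixels are insensitive calibration elements and are
#' masked without analysis; `edge_width` sets how many border pixels each
#' ASIC loses on every side.  The default layout is a 128 x 512 module made
#' of 2 x 8 ASICs of 64 x 64 pixels.
#'
#' @param asic_height,asic_width ASIC tile size in pixels.
#' @param n_asic_rows,n_asic_cols number of ASIC tiles per module side.
#' @param edge_width insensitive border width per ASIC, in pixels
#'   (default 1); must be less than half the smallest tile dimension.
#' @param module_id identifier attached to masks built from this layout.
#' @return An object of class `detector_layout`.
#' @examples
#' detector_layout()                      # AGIPD-like 128 x 512 module
#' detector_layout(64, 64, 1, 1)          # a single ASIC
#' @export
detector_layout <- function(asic_height = 64, asic_width = 64,
                            n_asic_rows = 2, n_asic_cols = 8,
                            edge_width = 1, module_id = "m0") {
  asic_height <- as.integer(asic_height)
  asic_width <- as.integer(asic_width)
  n_asic_rows <- as.integer(n_asic_rows)
  n_asic_cols <- as.integer(n_asic_cols)
  edge_width <- as.integer(edge_width)
  stopifnot(asic_height > 0, asic_width > 0, n_asic_rows > 0,
            n_asic_cols > 0, edge_width >= 0)
  if (edge_width >= min(asic_height, asic_width) / 2)
    stop("`edge_width` must be less than half the smallest ASIC dimension",
         call. = FALSE)
  structure(
    list(
      asic_height = asic_height, asic_width = asic_width,
      n_asic_rows = n_asic_rows, n_asic_cols = n_asic_cols,
      H = asic_height * n_asic_rows, W = asic_width * n_asic_cols,
      edge_width = edge_width, module_id = module_id
    ),
    class = "detector_layout"
  )
}

#' @export
print.detector_layout <- function(x, ...) {
  cat(sprintf(
    "<detector_layout>  %d x %d pixels = %d x %d ASICs of %d x %d (edge width %d)\n",
    x$H, x$W, x$n_asic_rows, x$n_asic_cols, x$asic_height, x$asic_width,
    x$edge_width))
  invisible(x)
}

# integer H x W matrix of 1-based ASIC ids (row-major over the ASIC grid)
asic_map <- function(layout) {
  ar <- (seq_len(layout$H) - 1L) %/% layout$asic_height
  ac <- (seq_len(layout$W) - 1L) %/% layout$asic_width
  outer(ar, ac, function(i, j) i * layout$n_asic_cols + j + 1L)
}

#' Logical matrix of ASIC-edge pixels
#'
#' `TRUE` for every pixel within `edge_width` pixels of any ASIC border.
#' These pixels are insensitive and are masked without analysis.
#'
#' @param layout a [detector_layout()].
#' @return Logical `H x W` matrix.
#' @export
edge_pixels <- function(layout) {
  stopifnot(inherits(layout, "detector_layout"))
  ew <- layout$edge_width
  out <- matrix(FALSE, layout$H, layout$W)
  if (ew == 0) return(out)
  rin <- (seq_len(layout$H) - 1L) %% layout$asic_height
  cin <- (seq_len(layout$W) - 1L) %% layout$asic_width
  row_edge <- rin < ew | rin >= layout$asic_height - ew
  col_edge <- cin < ew | cin >= layout$asic_width - ew
  out[row_edge, ] <- TRUE
  out[, col_edge] <- TRUE
  out
}

# ASIC-aligned tiles of at most tile_size pixels a side; tiles never straddle
# ASIC boundaries (each ASIC is subdivided into near-equal chunks)
tile_grid <- function(layout, tile_size = 64) {
  split_axis <- function(n_tiles, tile_len, size) {
    pieces <- max(1L, ceiling(tile_len / size))
    cuts <- round(seq(0L, tile_len, length.out = pieces + 1L))
    starts <- integer(0)
    ends <- integer(0)
    for (t in seq_len(n_tiles)) {
      off <- (t - 1L) * tile_len
      starts <- c(starts, off + cuts[-length(cuts)] + 1L)
      ends <- c(ends, off + cuts[-1L])
    }
    data.frame(start = starts, end = ends)
  }
  rows <- split_axis(layout$n_asic_rows, layout$asic_height, tile_size)
  cols <- split_axis(layout$n_asic_cols, layout$asic_width, tile_size)
  tiles <- vector("list", nrow(rows) * nrow(cols))
  k <- 1L
  for (i in seq_len(nrow(rows))) {
    for (j in seq_len(nrow(cols))) {
      tiles[[k]] <- list(r0 = rows$start[i], r1 = rows$end[i],
                         c0 = cols$start[j], c1 = cols$end[j])
      k <- k + 1L
    }
  }
  tiles
}
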