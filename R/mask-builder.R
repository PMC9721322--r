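#' Bit legend of the 8-bit pixel mask
#'
#' A mask code of 0 means a good pixel; each set bit identifies the feature
#' that flagged the pixel, and codes are the bitwise OR of all contributing
#' features so multi-feature flags are preserved.
#'
#' @format Named integer vector of bit positions:
#' \describe{
#'   \item{asic_edge (bit 0)}{ASIC border pixel, masked without analysis}
#'   \item{offset (bit 1)}{abnormal dark offset (F2)}
#'   \item{noise (bit 2)}{abnormal dark noise (F3)}
#'   \item{gain_separability (bit 3)}{indistinguishable gain stages (F4)}
#'   \item{gain_level (bit 4)}{abnormal gain-indicator level (F5)}
#'   \item{illuminated (bit 5)}{abnormal response under illumination (F6)}
#'   \item{not_evaluable (bit 6)}{could not be analysed; masked conservatively}
#'   \item{manual (bit 7)}{externally supplied manual mask, merged verbatim}
#' }
#' @export
mask_bits <- c(
  asic_edge = 0L,
  offset = 1L,
  noise = 2L,
  gain_separability = 3L,
  gain_level = 4L,
  illuminated = 5L,
  not_evaluable = 6L,
  manual = 7L
)

new_pixel_mask <- function(code, module_id = "m0", memory_cell = NA_integer_,
                           gain_stage = NA_character_) {
  storage.mode(code) <- "integer"
  structure(code, module_id = module_id,
            memory_cell = as.integer(memory_cell), gain_stage = gain_stage,
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<pixel_mask>  %d x %d pixels, %d bad (%.3g%%)\n",
              nrow(x), ncol(x), sum(x != 0L), 100 * sum(x != 0L) / n))
  invisible(x)
}

#' ASIC-edge mask contribution
#'
#' Every pixel within `edge_width` pixels of an ASIC border receives the
#' `asic_edge` bit.  For a single `h x w` ASIC with edge width 1 this flags
#' `2h + 2w - 4` pixels.
#'
#' @param layout a [detector_layout()].
#' @return A `pixel_mask` containing only the edge bit.
#' @examples
#' sum(edge_mask(detector_layout(64, 64, 1, 1)) != 0)  # 252
#' @export
edge_mask <- function(layout) {
  stopifnot(inherits(layout, "detector_layout"))
  code <- matrix(0L, layout$H, layout$W)
  code[edge_pixels(layout)] <- bitwShiftL(1L, mask_bits[["asic_edge"]])
  new_pixel_mask(code, module_id = layout$module_id)
}

#' Combine per-feature labels into an 8-bit pixel mask
#'
#' Contributions are OR-ed bitwise: a pixel is bad iff any feature flagged
#' it, and its code records every flagging feature.  The operation is
#' commutative, associative and idempotent.
#'
#' @param contributions list of contributions; each is either a
#'   `pixel_mask` (merged verbatim) or a `list(labels = <logical matrix>,
#'   bit = <bit name or number>)`.  `NA` labels are not flagged.
#' @param module_id,memory_cell,gain_stage metadata for the combined mask.
#' @return A `pixel_mask`.
#' @examples
#' lab <- matrix(FALSE, 4, 4); lab[2, 2] <- TRUE
#' m <- combine_masks(list(list(labels = lab, bit = "offset"),
#'                         list(labels = lab, bit = "illuminated")))
#' m[2, 2]  # 2^1 + 2^5 = 34
#' @export
combine_masks <- function(contributions, module_id = "m0",
                          memory_cell = NA_integer_,
                          gain_stage = NA_character_) {
  stopifnot(is.list(contributions))
  code <- NULL
  for (ctr in contributions) {
    if (inherits(ctr, "pixel_mask")) {
      add <- unclass(ctr)
    } else {
      bit <- ctr$bit
      if (is.character(bit)) bit <- mask_bits[[bit]]
      lab <- ctr$labels
      lab[is.na(lab)] <- FALSE
      add <- matrix(0L, nrow(lab), ncol(lab))
      add[lab] <- bitwShiftL(1L, as.integer(bit))
    }
    if (is.null(code)) {
      code <- matrix(0L, nrow(add), ncol(add))
    } else if (!identical(dim(code), dim(add))) {
      stop("mask contributions have mismatched pixel shapes", call. = FALSE)
    }
    code <- matrix(bitwOr(code, add), nrow(add), ncol(add))  # bitwOr drops dim
  }
  if (is.null(code)) stop("no contributions supplied", call. = FALSE)
  new_pixel_mask(code, module_id, memory_cell, gain_stage)
}

#' Collapse per-context masks into an any-context mask
#'
#' Bitwise OR over all (memory cell, gain stage) masks of a module: a pixel
#' is flagged if it is flagged in any context.
#'
#' @param masks list of `pixel_mask` objects of identical shape.
#' @return A `pixel_mask`.
#' @export
collapse_masks <- function(masks) {
  combine_masks(masks, module_id = attr(masks[[1]], "module_id"))
}

#' Summarize a pixel mask
#'
#' Counts per mask bit, the total bad fraction, and (if a layout is given) a
#' per-ASIC breakdown.
#'
#' @param mask a `pixel_mask`.
#' @param layout optional [detector_layout()] for the per-ASIC breakdown.
#' @return An object of class `mask_summary` with tibbles `by_bit` and
#'   (optionally) `by_asic`, plus `n_pixels`, `n_bad`, `fraction_bad`.
#' @export
summarize_mask <- function(mask, layout = NULL) {
  stopifnot(inherits(mask, "pixel_mask"))
  code <- unclass(mask)
  n <- length(code)
  by_bit <- tibble::tibble(
    bit = unname(mask_bits),
    flag = names(mask_bits),
    count = vapply(mask_bits, function(b) {
      sum(bitwAnd(code, bitwShiftL(1L, b)) != 0L)
    }, integer(1)),
  )
  by_bit$fraction <- by_bit$count / n
  out <- list(
    by_bit = by_bit,
    n_pixels = n,
    n_bad = sum(code != 0L),
    fraction_bad = sum(code != 0L) / n
  )
  if (!is.null(layout)) {
    am <- asic_map(layout)
    out$by_asic <- tibble::tibble(
      asic = seq_len(layout$n_asic_rows * layout$n_asic_cols),
      n_bad = as.integer(tapply(code != 0L, am, sum)),
      fraction_bad = as.numeric(tapply(code != 0L, am, mean))
    )
  }
  structure(out, class = "mask_summary")
}

#' @export
print.mask_summary <- function(x, ...) {
  cat(sprintf("<mask_summary>  %d pixels, %d bad (%.4g%%)\n",
              x$n_pixels, x$n_bad, 100 * x$fraction_bad))
  df <- as.data.frame(x$by_bit)
  df <- df[df$count > 0, , drop = FALSE]
  if (nrow(df)) print(df, row.names = FALSE)
  invisible(x)
}
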