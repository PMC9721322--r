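#' Detector frame stack
#'
#' A stack of detector frames for one (module, memory cell, gain stage)
#' context, stored as an `H x W x T` array (rows, columns, frames).
#' Non-finite entries are legal and are treated as pre-masked: they are
#' excluded from every temporal and population statistic, and pixels with
#' too few finite frames are flagged not-evaluable downstream.
#'
#' @param values numeric `H x W x T` array with `T >= 3` frames.
#' @param module_id identifier of the detector module.
#' @param memory_cell integer memory-cell index (0-based).
#' @param gain_stage `"high"`, `"medium"`, `"low"` or `"single"`.
#' @param kind `"analogue"` for pixel values, `"gain"` for gain-stage
#'   indicator values.
#' @return An object of class `frame_stack` (the array, with metadata
#'   attributes).
#' @export
frame_stack <- function(values, module_id = "m0", memory_cell = 0L,
                        gain_stage = c("high", "medium", "low", "single"),
                        kind = c("analogue", "gain")) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an H x W x T array", call. = FALSE)
  if (dim(values)[3] < 3)
    stop("a frame stack needs at least 3 frames", call. = FALSE)
  structure(
    values,
    module_id = module_id,
    memory_cell = as.integer(memory_cell),
    gain_stage = match.arg(gain_stage),
    kind = match.arg(kind),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<frame_stack>  %d x %d pixels, %d frames  (module %s, cell %d, %s gain, %s)\n",
    d[1], d[2], d[3], attr(x, "module_id"), attr(x, "memory_cell"),
    attr(x, "gain_stage"), attr(x, "kind")))
  nf <- sum(!is.finite(x))
  if (nf > 0) cat(sprintf("  pre-masked (non-finite) entries: %d\n", nf))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) NextMethod()

n_frames <- function(stack) dim(stack)[3]

# H*W x T matrix view (no copy semantics beyond dim change)
stack_matrix <- function(stack, frames = NULL) {
  d <- dim(stack)
  m <- matrix(as.numeric(stack), d[1] * d[2], d[3])
  if (!is.null(frames)) m <- m[, frames, drop = FALSE]
  m
}

# per-pixel temporal mean/sd/finite-count over the selected frames
temporal_stats <- function(stack, frames = NULL) {
  m <- stack_matrix(stack, frames)
  d <- dim(stack)
  st <- cpp_temporal_stats(m)
  list(
    mean = matrix(st$mean, d[1], d[2]),
    sd = matrix(st$sd, d[1], d[2]),
    n_finite = matrix(st$count, d[1], d[2]),
    n_frames = ncol(m)
  )
}
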