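# shared fixtures built in code

# 1-based linear indices of truth pixels of given classes
truth_idx <- function(truth, classes, H) {
  sel <- truth$class %in% classes
  (truth$col[sel] - 1L) * H + truth$row[sel]
}

# linear indices of normal (non-defect, non-edge) pixels
normal_idx <- function(truth, layout) {
  defects <- (truth$col - 1L) * layout$H + truth$row
  setdiff(which(!edge_pixels(layout)), defects)
}

# a small frame stack with given per-pixel offsets and iid noise
make_stack <- function(offsets, T, noise = 0, jitter = NULL, seed = 1,
                       ...) {
  set.seed(seed)
  H <- nrow(offsets); W <- ncol(offsets)
  m <- matrix(rnorm(H * W * T, 0, max(noise, 1e-12)), H * W, T) *
    (noise > 0)
  m <- m + as.vector(offsets)
  if (!is.null(jitter)) m <- m + rep(jitter, each = H * W)
  frame_stack(array(m, c(H, W, T)), ...)
}

# contaminated vector: n inliers N(mu, sigma) plus a fraction f of the total
# placed at mu + shift * sigma
contaminated <- function(n, mu, sigma, f, shift = 50, two_sided = FALSE) {
  x <- rnorm(n, mu, sigma)
  nc <- round(f / (1 - f) * n)
  if (nc > 0) {
    out <- rep(mu + shift * sigma, nc)
    if (two_sided && nc > 1) {
      half <- seq_len(nc %/% 2)
      out[half] <- mu - shift * sigma
    }
    x <- c(x, out)
  }
  x
}

# least-squares plane fit restricted to known-clean points (test oracle)
ls_plane <- function(rows, cols, values, keep = TRUE) {
  df <- data.frame(r = rows, c = cols, v = values)[keep, ]
  coef(lm(v ~ r + c, data = df))
}
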