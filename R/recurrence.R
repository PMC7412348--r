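#' Unthresholded recurrence plot of a force window
#'
#' Computes `P[i, j] = |x[i] - x[j]| / max(x)`: the matrix of normalized
#' pairwise absolute differences of the scalar series. No embedding, delay
#' or recurrence threshold is involved -- the encoding is the distance plot
#' itself, rendered later as a gray-level image where 0 (similar states) is
#' black. For a nonnegative signal the normalization by `max(x)` bounds all
#' entries in `[0, 1]`.
#'
#' @param x numeric force vector, length >= 2, elementwise nonnegative with
#'   `max(x) > 0`. An all-zero (or negative-peak) window is a degenerate
#'   signal and raises an error.
#' @param block_rows optional row-block size for bounded-memory computation
#'   of large plots; the result is identical for every block size.
#' @return object of class `recurrence_plot`: the n x n matrix `P` with
#'   attribute `n`.
#' @export
compute_rp <- function(x, block_rows = NULL) {
  if (!is.numeric(x) || length(x) < 2)
    stop_invalid("x must be a numeric vector of length >= 2")
  if (!all(is.finite(x))) stop_invalid("x must be finite")
  if (min(x) < 0)
    stop_invalid("x must be nonnegative (vGRF precondition); use min-max scaling upstream for signed signals")
  m <- max(x)
  if (m <= 0)
    stop_invalid("degenerate signal: max(x) must be > 0 (all-zero window)")
  n <- length(x)
  if (is.null(block_rows) || block_rows >= n) {
    P <- abs(outer(x, x, "-")) / m
  } else {
    P <- matrix(0, n, n)
    i <- 1L
    while (i <= n) {
      j <- min(i + block_rows - 1L, n)
      P[i:j, ] <- abs(outer(x[i:j], x, "-")) / m
      i <- j + 1L
    }
  }
  structure(P, class = c("recurrence_plot", "matrix"), n = n)
}

#' Resample a recurrence plot to a fixed gray-level image
#'
#' Bilinear resampling (pixel-center alignment) of the plot to a square
#' `resolution x resolution` image; values are clipped to `[0, 1]`.
#' Orientation: row i = time increasing downward, column j = time increasing
#' rightward; intensity equals the plot value, so 0 maps to black.
#'
#' @param rp a [compute_rp()] result or any numeric matrix in `[0, 1]`.
#' @param resolution output side length in pixels (>= 2); 227 matches the
#'   canonical input size of AlexNet-family feature extractors.
#' @return object of class `rp_image`: the resolution x resolution matrix.
#' @export
rp_to_image <- function(rp, resolution = 227) {
  stopifnot(is.matrix(rp))
  if (!is_count(resolution) || resolution < 2)
    stop_invalid("resolution must be an integer >= 2")
  A <- bilinear_weights(nrow(rp), resolution)
  B <- bilinear_weights(ncol(rp), resolution)
  img <- A %*% unclass(rp) %*% t(B)
  img <- pmin(pmax(img, 0), 1)
  structure(img, class = c("rp_image", "matrix"),
            resolution = as.integer(resolution))
}

# Row-interpolation matrix (n_out x n_src) for pixel-center aligned bilinear
# resampling: output center i maps to source coordinate
# (i - 0.5) * n_src/n_out + 0.5, clamped to the grid. n_out == n_src gives
# the identity.
bilinear_weights <- function(n_src, n_out) {
  W <- matrix(0, n_out, n_src)
  s <- (seq_len(n_out) - 0.5) * n_src / n_out + 0.5
  s <- pmin(pmax(s, 1), n_src)
  i0 <- pmin(floor(s), n_src - 1)
  if (n_src == 1) i0 <- rep(1, n_out)
  f <- s - i0
  for (k in seq_len(n_out)) {
    W[k, i0[k]] <- W[k, i0[k]] + (1 - f[k])
    W[k, min(i0[k] + 1, n_src)] <- W[k, min(i0[k] + 1, n_src)] + f[k]
  }
  W
}
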