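#' Bilinear interpolation of a raster at continuous pixel coordinates
#'
#' @param mat numeric matrix (rows = y, cols = x).
#' @param x_px,y_px 0-based fractional pixel coordinates (x along columns).
#' @return numeric vector of interpolated values; coordinates are clamped to
#'   the raster.
#' @keywords internal
#' @noRd
sample_bilinear <- function(mat, x_px, y_px) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  x <- pmin(pmax(x_px, 0), nc - 1)
  y <- pmin(pmax(y_px, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2)
  y0 <- pmin(floor(y), nr - 2)
  tx <- x - x0
  ty <- y - y0
  i0 <- y0 + 1
  j0 <- x0 + 1
  v00 <- mat[cbind(i0, j0)]
  v01 <- mat[cbind(i0, j0 + 1)]
  v10 <- mat[cbind(i0 + 1, j0)]
  v11 <- mat[cbind(i0 + 1, j0 + 1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Wrap angles to (-pi, pi]
#' @keywords internal
#' @noRd
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

#' Interleave x/y component vectors into a single stacked vector
#' @keywords internal
#' @noRd
interleave_xy <- function(x, y) {
  as.vector(rbind(x, y))
}

#' Split a stacked interleaved vector into x and y components
#' @keywords internal
#' @noRd
split_xy <- function(v) {
  list(x = v[seq(1, length(v), by = 2)], y = v[seq(2, length(v), by = 2)])
}

#' Derive reproducible sub-seeds from one seed
#' @keywords internal
#' @noRd
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}
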