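#' Inward force direction field from a smoothed level set
#'
#' Samples the negative normalized gradient of the (typically MCF-evolved)
#' level-set function at the force grid points that lie inside the original
#' cell mask: unit vectors pointing toward decreasing phi, i.e. inward.
#' Gradients are central differences on the raster, bilinearly interpolated
#' at grid-point positions and then normalized. Points where the gradient
#' magnitude falls below 1e-8 (the skeleton/ridge of the distance function)
#' get a zero vector and are flagged.
#'
#' @param ls a `level_set` (evolved by [evolve_mcf()] or raw).
#' @param mask the original [cell_mask()]; directions are only defined
#'   inside it ("cut out" of the smoothed surface).
#' @param grid a [force_grid()].
#' @param smooth_sigma Gaussian smoothing width (pixels) applied to phi
#'   before gradients are taken; removes the faceting of the discrete
#'   distance transform. Default 2.
#' @return The grid tibble with columns `dx`, `dy` (unit vector inside the
#'   mask, 0 outside) and `degenerate` (TRUE where the gradient vanished).
#' @export
direction_field <- function(ls, mask, grid, smooth_sigma = 2) {
  stopifnot(inherits(ls, "level_set"), inherits(mask, "cell_mask"),
            inherits(grid, "force_grid"))
  if (!all(dim(ls$phi) == dim(mask$raster)) || ls$pixel_size != mask$pixel_size)
    stop("level set and mask rasters do not share geometry", call. = FALSE)
  px <- ls$pixel_size
  phi_s <- if (smooth_sigma > 0) {
    as.matrix(EBImage::gblur(ls$phi, sigma = smooth_sigma))
  } else {
    ls$phi
  }
  gx_r <- (shift_cols(phi_s, 1) - shift_cols(phi_s, -1)) / (2 * px)
  gy_r <- (shift_rows(phi_s, 1) - shift_rows(phi_s, -1)) / (2 * px)
  xpx <- grid$x_um / px
  ypx <- grid$y_um / px
  gx <- sample_bilinear(gx_r, xpx, ypx)
  gy <- sample_bilinear(gy_r, xpx, ypx)
  nrm <- sqrt(gx^2 + gy^2)
  deg <- nrm < 1e-8
  nrm[deg] <- 1
  out <- grid
  keep <- grid$inside_cell & !deg
  out$dx <- ifelse(keep, -gx / nrm, 0)
  out$dy <- ifelse(keep, -gy / nrm, 0)
  out$degenerate <- grid$inside_cell & deg
  out
}

#' Boundary-decay force magnitude field
#'
#' Prior force magnitude m(r) = exp(-r^2 / sigma^2) with r the inward
#' distance from the cell boundary and sigma^2 a fixed fraction of the cell
#' area (default 10%): larger cells generate force over a wider band along
#' their boundary. m = 1 on the boundary, decays inward, and is 0 outside
#' the mask.
#'
#' @param mask a [cell_mask()].
#' @param grid a [force_grid()].
#' @param sigma2_fraction sigma^2 as a fraction of cell area (default 0.1).
#' @param sdf optional precomputed [signed_distance()] of `mask`.
#' @return The grid tibble with column `m` in `[0, 1]` and attribute
#'   `sigma2` (um^2).
#' @export
magnitude_field <- function(mask, grid, sigma2_fraction = 0.1, sdf = NULL) {
  stopifnot(inherits(mask, "cell_mask"), inherits(grid, "force_grid"),
            sigma2_fraction > 0)
  if (is.null(sdf)) sdf <- signed_distance(mask)
  px <- mask$pixel_size
  phi <- sample_bilinear(sdf$phi, grid$x_um / px, grid$y_um / px)
  r_in <- pmax(-phi, 0)
  sigma2 <- sigma2_fraction * mask_area(mask)
  out <- grid
  out$m <- ifelse(grid$inside_cell, exp(-r_in^2 / sigma2), 0)
  attr(out, "sigma2") <- sigma2
  out
}

#' Prior center field: magnitude times inward direction
#'
#' f_mu(x) = scale * m(x) * d(x) at every grid point, zero outside the cell.
#'
#' @param m magnitude tibble from [magnitude_field()].
#' @param d direction tibble from [direction_field()].
#' @param scale global prior force scale (stress units; default 1 — the
#'   per-point magnitude corrections learned during estimation absorb any
#'   global scale).
#' @return The grid tibble with columns `m`, `dx`, `dy`, `fmux`, `fmuy`.
#' @export
prior_center <- function(m, d, scale = 1) {
  stopifnot("m" %in% names(m), all(c("dx", "dy") %in% names(d)))
  if (nrow(m) != nrow(d) ||
      any(m$grid_i != d$grid_i) || any(m$grid_j != d$grid_j))
    stop("magnitude and direction fields are on different grids", call. = FALSE)
  out <- m
  out$dx <- d$dx
  out$dy <- d$dy
  if ("degenerate" %in% names(d)) out$degenerate <- d$degenerate
  out$fmux <- scale * out$m * out$dx
  out$fmuy <- scale * out$m * out$dy
  out
}

#' Full cell-boundary force prior
#'
#' Convenience pipeline: signed distance -> mean curvature flow for time
#' `tau` -> inward direction field restricted to the original mask, combined
#' with the boundary-decay magnitude into the prior center field.
#'
#' @param mask a [cell_mask()].
#' @param grid a [force_grid()].
#' @param tau MCF evolution time (pixel^2); default [default_mcf_tau()].
#' @param sigma2_fraction sigma^2 as a fraction of cell area.
#' @param scale global prior force scale.
#' @param dt,reinit_every MCF integration controls, see [evolve_mcf()].
#' @return Prior tibble as from [prior_center()], with attributes `sigma2`
#'   and `tau`.
#' @export
boundary_prior <- function(mask, grid, tau = default_mcf_tau(mask),
                           sigma2_fraction = 0.1, scale = 1,
                           dt = 0.2, reinit_every = 20) {
  sdf <- signed_distance(mask)
  ls_tau <- evolve_mcf(sdf, tau = tau, dt = dt, reinit_every = reinit_every)
  d <- direction_field(ls_tau, mask, grid)
  m <- magnitude_field(mask, grid, sigma2_fraction = sigma2_fraction, sdf = sdf)
  out <- prior_center(m, d, scale = scale)
  attr(out, "sigma2") <- attr(m, "sigma2")
  attr(out, "tau") <- tau
  out
}
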