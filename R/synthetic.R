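#' Rasterize a closed polygon to a cell mask
#'
#' Even-odd (crossing-number) test of each pixel center against the polygon.
#'
#' @param vertices two-column matrix or data frame of vertex coordinates
#'   (um), in order; the polygon is closed implicitly.
#' @param dim raster dimensions c(rows, cols).
#' @param pixel_size um per pixel.
#' @return A [cell_mask()].
#' @export
rasterize_polygon <- function(vertices, dim, pixel_size) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 3)
  nr <- dim[1]
  nc <- dim[2]
  xs <- (seq_len(nc) - 1) * pixel_size
  ys <- (seq_len(nr) - 1) * pixel_size
  px <- rep(xs, each = nr)
  py <- rep(ys, times = nc)
  inside <- rep(FALSE, nr * nc)
  nv <- nrow(v)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  cell_mask(matrix(inside, nr, nc), pixel_size)
}

#' Generate a model cell boundary
#'
#' Geometric shapes (circle, square, equilateral triangle, X) probe the
#' effect of boundary symmetry; `blob` generates a smoothed random Fourier
#' perturbation of a circle as a synthetic stand-in for irregular outlines
#' of real motile cells. Low `amplitude` gives near-round cells, high
#' amplitude lobed, complex ones.
#'
#' @param kind one of "circle", "square", "triangle", "x_shape", "blob".
#' @param dim raster dimensions c(rows, cols) in pixels (default 256 x 256).
#' @param pixel_size um per pixel (default 0.2).
#' @param size characteristic size in um: circle/blob radius, square or
#'   triangle side, X arm length. Default scales with the field (radius 30%
#'   of the field width; side/arm chosen for comparable area).
#' @param amplitude blob perturbation amplitude (fraction of radius) for
#'   `kind = "blob"`; default 0.35 (complex). Use ~0.08 for near-round.
#' @param n_harmonics number of Fourier harmonics (k = 2 ... n_harmonics+1)
#'   perturbing the blob radius.
#' @param seed integer seed (blob only; other shapes are deterministic).
#' @return A [cell_mask()].
#' @examples
#' m <- generate_boundary("blob", dim = c(96, 96), seed = 3)
#' @export
generate_boundary <- function(kind = c("circle", "square", "triangle",
                                       "x_shape", "blob"),
                              dim = c(256, 256), pixel_size = 0.2,
                              size = NULL, amplitude = 0.35,
                              n_harmonics = 5, seed = NULL) {
  kind <- match.arg(kind)
  nr <- dim[1]
  nc <- dim[2]
  W <- nc * pixel_size
  H <- nr * pixel_size
  span <- min(W, H)
  cx <- (nc - 1) / 2 * pixel_size
  cy <- (nr - 1) / 2 * pixel_size
  xs <- (seq_len(nc) - 1) * pixel_size
  ys <- (seq_len(nr) - 1) * pixel_size
  X <- matrix(rep(xs, each = nr), nr, nc) - cx
  Y <- matrix(rep(ys, times = nc), nr, nc) - cy

  raster <- switch(kind,
    circle = {
      R <- if (is.null(size)) 0.3 * span else size
      if (R >= span / 2) stop("circle exceeds the raster", call. = FALSE)
      X^2 + Y^2 <= R^2
    },
    square = {
      s <- if (is.null(size)) 0.53 * span else size
      if (s >= span) stop("square exceeds the raster", call. = FALSE)
      abs(X) <= s / 2 & abs(Y) <= s / 2
    },
    triangle = {
      s <- if (is.null(size)) 0.8 * span else size
      h <- s * sqrt(3) / 2
      if (h >= H || s >= W) stop("triangle exceeds the raster", call. = FALSE)
      # equilateral triangle, centroid at field center, apex up (-y)
      verts <- rbind(c(cx, cy - 2 * h / 3),
                     c(cx - s / 2, cy + h / 3),
                     c(cx + s / 2, cy + h / 3))
      return(rasterize_polygon(verts, dim, pixel_size))
    },
    x_shape = {
      L <- if (is.null(size)) 0.7 * span else size
      w <- L / 4
      if (L / sqrt(2) >= span / 1) stop("X shape exceeds the raster",
                                        call. = FALSE)
      c45 <- cos(pi / 4); s45 <- sin(pi / 4)
      u1 <- c45 * X + s45 * Y; v1 <- -s45 * X + c45 * Y
      u2 <- c45 * X - s45 * Y; v2 <- s45 * X + c45 * Y
      (abs(u1) <= L / 2 & abs(v1) <= w / 2) |
        (abs(u2) <= L / 2 & abs(v2) <= w / 2)
    },
    blob = {
      R <- if (is.null(size)) 0.3 * span else size
      ks <- seq(2, 1 + n_harmonics)
      coefs <- withr::with_seed(if (is.null(seed)) 0L else seed, list(
        a = amplitude * stats::rnorm(length(ks)) / sqrt(length(ks)),
        phase = stats::runif(length(ks), 0, 2 * pi)))
      theta <- atan2(Y, X)
      rho <- sqrt(X^2 + Y^2)
      rb <- matrix(R, nr, nc)
      for (i in seq_along(ks))
        rb <- rb + R * coefs$a[i] * cos(ks[i] * theta + coefs$phase[i])
      rb <- pmin(pmax(rb, 0.25 * R), 0.49 * span)
      rho <= rb
    })
  cell_mask(raster, pixel_size, largest_component = TRUE)
}

#' Sample sparse inward traction forces on the grid
#'
#' Picks `n_forces` distinct interior grid points with sampling weight equal
#' to the boundary-decay magnitude field (forces concentrate near the
#' boundary, where actin-driven traction arises), and assigns each an
#' inward force: the prior direction rotated by Gaussian angular noise,
#' scaled by a lognormally jittered magnitude.
#'
#' @param mask a [cell_mask()].
#' @param grid a [force_grid()].
#' @param n_forces number of force points (default 20).
#' @param magnitude mean force magnitude (stress units; default 10).
#' @param direction_noise_sd angular noise sd in radians (default 0.2).
#' @param magnitude_jitter_sdlog lognormal sdlog of the magnitude jitter
#'   (default 0.2, about +-20%).
#' @param prior optional precomputed [boundary_prior()] on `grid`.
#' @param seed integer seed.
#' @return Force-field tibble: grid columns plus `fx`, `fy`, nonzero at
#'   exactly `n_forces` points, all inside the mask.
#' @export
sample_traction_forces <- function(mask, grid, n_forces = 20, magnitude = 10,
                                   direction_noise_sd = 0.2,
                                   magnitude_jitter_sdlog = 0.2,
                                   prior = NULL, seed = NULL) {
  if (is.null(prior)) prior <- boundary_prior(mask, grid)
  forces <- grid
  forces$fx <- 0
  forces$fy <- 0
  if (n_forces == 0) return(forces)
  eligible <- which(prior$inside_cell & !prior$degenerate & prior$m > 0)
  if (length(eligible) < n_forces)
    stop(sprintf("only %d eligible interior grid points for %d forces",
                 length(eligible), n_forces), call. = FALSE)
  draw <- function() {
    idx <- sample(eligible, n_forces, prob = prior$m[eligible])
    ang <- if (direction_noise_sd > 0)
      stats::rnorm(n_forces, 0, direction_noise_sd) else rep(0, n_forces)
    mag <- magnitude * stats::rlnorm(n_forces,
                                     -magnitude_jitter_sdlog^2 / 2,
                                     magnitude_jitter_sdlog)
    list(idx = idx, ang = ang, mag = mag)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dx <- prior$dx[d$idx]
  dy <- prior$dy[d$idx]
  forces$fx[d$idx] <- d$mag * (cos(d$ang) * dx - sin(d$ang) * dy)
  forces$fy[d$idx] <- d$mag * (sin(d$ang) * dx + cos(d$ang) * dy)
  forces
}

#' Scatter beads uniformly over the substrate field
#'
#' Uniform random bead positions over the image field; the count is
#' round(density x field area). Beads falling within `min_dist` of a force
#' grid node are redrawn (the Green kernel diverges at zero offset).
#'
#' @param grid a [force_grid()] (defines the field extent and nodes).
#' @param density beads per um^2 (benchmark values: 0.4 low, 1.6 middle).
#' @param seed integer seed.
#' @param min_dist minimum bead-to-node distance in um.
#' @return Bead tibble: `bead_id`, `x_um`, `y_um` (no displacements yet).
#' @export
scatter_beads <- function(grid, density, seed = NULL, min_dist = 1e-6) {
  stopifnot(inherits(grid, "force_grid"), density > 0)
  ext <- attr(grid, "field_extent")
  area <- ext[["width"]] * ext[["height"]]
  n <- round(density * area)
  lo_x <- min(grid$x_um); hi_x <- max(grid$x_um)
  lo_y <- min(grid$y_um); hi_y <- max(grid$y_um)
  draw <- function() {
    x <- stats::runif(n, lo_x, hi_x)
    y <- stats::runif(n, lo_y, hi_y)
    for (iter in 1:20) {
      dx2 <- outer(x, grid$x_um, "-")^2
      dy2 <- outer(y, grid$y_um, "-")^2
      bad <- apply(dx2 + dy2 < min_dist^2, 1, any)
      if (!any(bad)) break
      x[bad] <- stats::runif(sum(bad), lo_x, hi_x)
      y[bad] <- stats::runif(sum(bad), lo_y, hi_y)
    }
    list(x = x, y = y)
  }
  p <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(bead_id = seq_len(n), x_um = p$x, y_um = p$y)
}

#' Synthetic benchmark configuration
#'
#' Bundles every knob of the synthetic TFM benchmark with the study
#' defaults: 20 noisy inward traction points, uniformly scattered beads at
#' 0.4 beads/um^2, Boussinesq forward displacements, and Gaussian
#' observation noise of sd 0.1 um.
#'
#' @param shape boundary kind, see [generate_boundary()].
#' @param field_px raster side length in pixels (square field, default 256).
#' @param pixel_size um per pixel (default 0.2).
#' @param boundary_size,blob_amplitude boundary size parameters.
#' @param grid_rows,grid_cols force grid (default 30 x 30).
#' @param n_forces,force_magnitude,direction_noise_sd,magnitude_jitter_sdlog
#'   traction sampling parameters, see [sample_traction_forces()].
#' @param bead_density beads per um^2.
#' @param noise_sd bead displacement observation noise sd (um).
#' @param youngs_modulus,poisson_ratio substrate parameters.
#' @return A list of class `tfm_config`.
#' @export
tfm_config <- function(shape = "blob", field_px = 256, pixel_size = 0.2,
                       boundary_size = NULL, blob_amplitude = 0.35,
                       grid_rows = 30, grid_cols = 30,
                       n_forces = 20, force_magnitude = 10,
                       direction_noise_sd = 0.2,
                       magnitude_jitter_sdlog = 0.2,
                       bead_density = 0.4, noise_sd = 0.1,
                       youngs_modulus = 1, poisson_ratio = 0.5) {
  cfg <- list(shape = shape, field_px = field_px, pixel_size = pixel_size,
              boundary_size = boundary_size, blob_amplitude = blob_amplitude,
              grid_rows = grid_rows, grid_cols = grid_cols,
              n_forces = n_forces, force_magnitude = force_magnitude,
              direction_noise_sd = direction_noise_sd,
              magnitude_jitter_sdlog = magnitude_jitter_sdlog,
              bead_density = bead_density, noise_sd = noise_sd,
              youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio)
  stopifnot(cfg$field_px >= 16, cfg$pixel_size > 0, cfg$n_forces >= 0,
            cfg$bead_density > 0, cfg$noise_sd >= 0)
  structure(cfg, class = "tfm_config")
}

#' Generate a full synthetic TFM dataset
#'
#' Chains boundary -> prior -> sparse inward forces -> random beads ->
#' Boussinesq forward displacements -> observation noise. Four sub-seeds
#' (boundary, forces, beads, noise) are derived deterministically from
#' `seed`, so the dataset is reproducible bit-exactly.
#'
#' @param config a [tfm_config()].
#' @param seed integer master seed.
#' @return An object of class `tfm_dataset`: `mask`, `grid`, `prior`,
#'   `true_forces`, `beads` (with noisy `ux_um`, `uy_um`),
#'   `clean_displacements`, `substrate`, `seeds`, `config`.
#' @export
make_dataset <- function(config = tfm_config(), seed = 1) {
  stopifnot(inherits(config, "tfm_config"))
  seeds <- derive_seeds(seed, 4)
  names(seeds) <- c("boundary", "forces", "beads", "noise")
  mask <- generate_boundary(config$shape,
                            dim = c(config$field_px, config$field_px),
                            pixel_size = config$pixel_size,
                            size = config$boundary_size,
                            amplitude = config$blob_amplitude,
                            seed = seeds[["boundary"]])
  grid <- force_grid(mask, rows = config$grid_rows, cols = config$grid_cols)
  prior <- boundary_prior(mask, grid)
  true_forces <- sample_traction_forces(
    mask, grid, n_forces = config$n_forces,
    magnitude = config$force_magnitude,
    direction_noise_sd = config$direction_noise_sd,
    magnitude_jitter_sdlog = config$magnitude_jitter_sdlog,
    prior = prior, seed = seeds[["forces"]])
  substrate <- elastic_substrate(config$youngs_modulus, config$poisson_ratio)
  ds <- structure(list(mask = mask, grid = grid, prior = prior,
                       true_forces = true_forces, substrate = substrate,
                       seeds = seeds, config = config),
                  class = "tfm_dataset")
  resample_beads(ds, bead_seed = seeds[["beads"]],
                 noise_seed = seeds[["noise"]])
}

#' Redraw bead positions (and noise) for an existing dataset
#'
#' Keeps the boundary, prior, and true forces fixed and regenerates the
#' bead scatter and its noisy displacements — one benchmark "replicate".
#'
#' @param ds a `tfm_dataset`.
#' @param bead_seed,noise_seed integer seeds for the scatter and the noise.
#' @return The dataset with new `beads` and `clean_displacements`.
#' @export
resample_beads <- function(ds, bead_seed, noise_seed = bead_seed + 1L) {
  stopifnot(inherits(ds, "tfm_dataset"))
  beads <- scatter_beads(ds$grid, ds$config$bead_density, seed = bead_seed)
  G <- assemble_greens_matrix(beads, ds$grid, ds$substrate)
  u_clean <- forward_displacements(G, ds$true_forces)
  u_obs <- add_observation_noise(u_clean, ds$config$noise_sd,
                                 seed = noise_seed)
  uxy <- split_xy(u_obs)
  beads$ux_um <- uxy$x
  beads$uy_um <- uxy$y
  ds$beads <- beads
  ds$clean_displacements <- u_clean
  ds$seeds[["beads"]] <- bead_seed
  ds$seeds[["noise"]] <- noise_seed
  ds
}

#' @export
print.tfm_dataset <- function(x, ...) {
  cat(sprintf(
    "<tfm_dataset> %s boundary, %d force points, %d beads (%.1f /um^2), noise sd %g um\n",
    x$config$shape, sum(x$true_forces$fx != 0 | x$true_forces$fy != 0),
    nrow(x$beads), x$config$bead_density, x$config$noise_sd))
  invisible(x)
}
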