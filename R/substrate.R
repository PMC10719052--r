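#' Elastic substrate parameters
#'
#' The substrate is modeled as a linear, isotropic, homogeneous elastic
#' half-space characterized by its Young's modulus and Poisson ratio.
#'
#' @param youngs_modulus Young's modulus E > 0. Units are free as long as
#'   forces are expressed in the same stress unit (only f/E enters the
#'   forward model); the default 1 means "forces in units of E".
#' @param poisson_ratio Poisson ratio, 0 < nu <= 0.5. Defaults to 0.5
#'   (incompressible gel).
#' @return An object of class `elastic_substrate`.
#' @examples
#' elastic_substrate(youngs_modulus = 1, poisson_ratio = 0.5)
#' @export
elastic_substrate <- function(youngs_modulus = 1, poisson_ratio = 0.5) {
  stopifnot(is.numeric(youngs_modulus), length(youngs_modulus) == 1,
            is.numeric(poisson_ratio), length(poisson_ratio) == 1)
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("`youngs_modulus` must be a positive finite number", call. = FALSE)
  if (!is.finite(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio > 0.5)
    stop("`poisson_ratio` must lie in (0, 0.5]", call. = FALSE)
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "elastic_substrate")
}

#' @export
print.elastic_substrate <- function(x, ...) {
  cat("<elastic_substrate> E =", x$youngs_modulus,
      " nu =", x$poisson_ratio, "\n")
  invisible(x)
}

#' Boussinesq-Green tensor for a tangential point force on a half-space
#'
#' Surface displacement response at in-plane offset `offset` from a
#' tangential point force on the surface of an elastic half-space:
#' \deqn{G(x) = \frac{1-\nu}{\pi E r^3}
#'   \begin{pmatrix} (1-\nu) r^2 + \nu x^2 & \nu x y \\
#'                   \nu x y & (1-\nu) r^2 + \nu y^2 \end{pmatrix}}
#' with \eqn{r = |x|}. The tensor is symmetric, even in the offset, and its
#' magnitude decays as 1/r.
#'
#' @param offset length-2 numeric, in-plane offset (um) from the force
#'   point to the observation point. Must be nonzero: the kernel diverges
#'   at r = 0.
#' @param substrate an [elastic_substrate()].
#' @return A symmetric 2x2 matrix (um displacement per unit stress x area).
#' @examples
#' greens_tensor(c(1, 1), elastic_substrate(1, 0.5))
#' @export
greens_tensor <- function(offset, substrate) {
  stopifnot(inherits(substrate, "elastic_substrate"),
            is.numeric(offset), length(offset) == 2)
  x <- offset[1]
  y <- offset[2]
  r2 <- x^2 + y^2
  if (r2 == 0)
    stop("Green tensor is singular at zero offset (bead on force point)",
         call. = FALSE)
  nu <- substrate$poisson_ratio
  E <- substrate$youngs_modulus
  pref <- (1 - nu) / (pi * E * r2^1.5)
  pref * matrix(c((1 - nu) * r2 + nu * x^2, nu * x * y,
                  nu * x * y, (1 - nu) * r2 + nu * y^2), 2, 2)
}

#' Force-estimation grid over the image field
#'
#' Lays a regular `rows` x `cols` grid of force points over the bounding
#' box of the mask raster. A grid point is flagged as inside the cell when
#' the mask pixel containing it is foreground. The cell area (foreground
#' pixels x pixel area) is attached: the forward model weights each force
#' point by A/N, the share of cell area per grid point.
#'
#' @param mask a [cell_mask()].
#' @param rows,cols grid dimensions (default 30 x 30, N = 900).
#' @return A tibble of class `force_grid` with columns `grid_i`, `grid_j`
#'   (0-based row/column of the grid), `x_um`, `y_um`, `inside_cell`, and
#'   attributes `cell_area` (um^2), `n_points`, `field_extent`.
#' @export
force_grid <- function(mask, rows = 30, cols = 30) {
  stopifnot(inherits(mask, "cell_mask"), rows >= 2, cols >= 2)
  px <- mask$pixel_size
  nr <- nrow(mask$raster)
  nc <- ncol(mask$raster)
  # field spans [-px/2, (nc - 1/2) px] x [-px/2, (nr - 1/2) px]
  xs <- (-0.5 + (seq_len(cols) - 0.5) * nc / cols) * px
  ys <- (-0.5 + (seq_len(rows) - 0.5) * nr / rows) * px
  g <- tidyr::expand_grid(grid_i = seq_len(rows) - 1L,
                          grid_j = seq_len(cols) - 1L)
  g$x_um <- xs[g$grid_j + 1L]
  g$y_um <- ys[g$grid_i + 1L]
  ri <- pmin(pmax(round(g$y_um / px), 0), nr - 1) + 1L
  ci <- pmin(pmax(round(g$x_um / px), 0), nc - 1) + 1L
  g$inside_cell <- mask$raster[cbind(ri, ci)]
  area <- sum(mask$raster) * px^2
  structure(g,
            cell_area = area,
            n_points = nrow(g),
            field_extent = c(width = nc * px, height = nr * px),
            class = c("force_grid", class(g)))
}

#' Assemble the discretized Boussinesq-Green matrix
#'
#' Builds the 2B x 2N linear map from stacked point forces (stress at the N
#' grid points) to stacked displacements at the B bead positions. Block
#' (i, n) is (A/N) G(x_i - x'_n) with A the cell area. Rows and columns
#' interleave x/y components per point.
#'
#' @param beads bead tibble with columns `x_um`, `y_um` (see [read_beads()]).
#' @param grid a [force_grid()].
#' @param substrate an [elastic_substrate()].
#' @param min_dist minimum allowed bead-to-grid-point distance (um); closer
#'   pairs raise an error since the kernel diverges.
#' @return A 2B x 2N matrix with attribute `prefactor` = A/N.
#' @export
assemble_greens_matrix <- function(beads, grid, substrate, min_dist = 1e-6) {
  stopifnot(inherits(grid, "force_grid"), inherits(substrate, "elastic_substrate"))
  bx <- beads$x_um
  by <- beads$y_um
  B <- length(bx)
  stopifnot(B >= 1)
  gx <- grid$x_um
  gy <- grid$y_um
  N <- nrow(grid)
  dx <- outer(bx, gx, "-")
  dy <- outer(by, gy, "-")
  r2 <- dx^2 + dy^2
  if (any(r2 < min_dist^2)) {
    k <- which(r2 < min_dist^2, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "bead %d lies within %g um of force grid point %d (distance %g um)",
      k[1], min_dist, k[2], sqrt(r2[k[1], k[2]])), call. = FALSE)
  }
  nu <- substrate$poisson_ratio
  E <- substrate$youngs_modulus
  A <- attr(grid, "cell_area")
  pref <- (A / N) * (1 - nu) / (pi * E) / r2^1.5
  G <- matrix(0, 2 * B, 2 * N)
  odd_r <- seq(1, 2 * B, by = 2)
  odd_c <- seq(1, 2 * N, by = 2)
  G[odd_r, odd_c] <- pref * ((1 - nu) * r2 + nu * dx^2)
  G[odd_r + 1, odd_c + 1] <- pref * ((1 - nu) * r2 + nu * dy^2)
  off <- pref * nu * dx * dy
  G[odd_r, odd_c + 1] <- off
  G[odd_r + 1, odd_c] <- off
  attr(G, "prefactor") <- A / N
  G
}

#' Forward displacements from a force field
#'
#' Applies the linear forward model u = G f. `forces` may be a stacked
#' 2N vector (interleaved x/y) or a force-field tibble with `fx`, `fy`
#' columns.
#'
#' @param G Green's matrix from [assemble_greens_matrix()].
#' @param forces numeric vector of length 2N, or tibble with `fx`, `fy`.
#' @return Stacked displacement vector of length 2B (um), interleaved x/y.
#' @export
forward_displacements <- function(G, forces) {
  f <- forces_as_vector(forces)
  if (length(f) != ncol(G))
    stop(sprintf("force vector length %d does not match ncol(G) = %d",
                 length(f), ncol(G)), call. = FALSE)
  drop(G %*% f)
}

#' @keywords internal
#' @noRd
forces_as_vector <- function(forces) {
  if (is.data.frame(forces)) {
    stopifnot(all(c("fx", "fy") %in% names(forces)))
    interleave_xy(forces$fx, forces$fy)
  } else {
    as.numeric(forces)
  }
}

#' Add Gaussian observation noise to a displacement vector
#'
#' Independent zero-mean Gaussian noise of the given standard deviation is
#' added to every displacement component, emulating bead-localization noise.
#'
#' @param u stacked displacement vector (um).
#' @param sd noise standard deviation (um), >= 0. The benchmark default is
#'   0.1 um.
#' @param seed optional integer seed; the global RNG state is preserved.
#' @return Noisy displacement vector of the same length.
#' @export
add_observation_noise <- function(u, sd, seed = NULL) {
  stopifnot(is.numeric(u), is.numeric(sd), length(sd) == 1)
  if (!is.finite(sd) || sd < 0)
    stop("noise `sd` must be a nonnegative finite number", call. = FALSE)
  if (sd == 0) return(u)
  noise <- if (is.null(seed)) {
    stats::rnorm(length(u), 0, sd)
  } else {
    withr::with_seed(seed, stats::rnorm(length(u), 0, sd))
  }
  u + noise
}
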