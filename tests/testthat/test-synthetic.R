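test_that("geometric boundaries have the requested area and symmetry", {
  px <- 0.25
  m <- generate_boundary("circle", dim = c(96, 96), pixel_size = px, size = 8)
  expect_lt(abs(mask_area(m) - pi * 8^2) / (pi * 8^2), 0.02)
  sq <- generate_boundary("square", dim = c(96, 96), pixel_size = px,
                          size = 10)
  expect_lt(abs(mask_area(sq) - 100) / 100, 0.02)
  # square mask is invariant under 90 degree rotation
  r <- sq$raster
  expect_identical(r, t(r[nrow(r):1, ]))
  tr <- generate_boundary("triangle", dim = c(96, 96), pixel_size = px,
                          size = 12)
  expect_lt(abs(mask_area(tr) - sqrt(3) / 4 * 144) / (sqrt(3) / 4 * 144),
            0.03)
  xs <- generate_boundary("x_shape", dim = c(96, 96), pixel_size = px)
  expect_gt(mask_area(xs), 0)
  expect_error(generate_boundary("circle", dim = c(32, 32), pixel_size = px,
                                 size = 10), "exceeds")
})

test_that("blob boundaries are reproducible and respond to amplitude", {
  b1 <- generate_boundary("blob", dim = c(96, 96), pixel_size = 0.25,
                          seed = 5)
  b2 <- generate_boundary("blob", dim = c(96, 96), pixel_size = 0.25,
                          seed = 5)
  expect_identical(b1$raster, b2$raster)
  b3 <- generate_boundary("blob", dim = c(96, 96), pixel_size = 0.25,
                          seed = 6)
  expect_false(identical(b1$raster, b3$raster))
  # near-round blobs deviate little from their circle-equivalent radius
  round_b <- generate_boundary("blob", dim = c(96, 96), pixel_size = 0.25,
                               amplitude = 0.05, seed = 5)
  sdf <- signed_distance(round_b)
  r_eq <- sqrt(mask_area(round_b) / pi)
  expect_lt(max(-sdf$phi) / r_eq, 1.25)
})

test_that("sampled traction forces sit inside the cell and point inward", {
  mask <- circle_mask(dim = 64, R_px = 24, px = 0.5)
  grid <- force_grid(mask, 20, 20)
  pr <- boundary_prior(mask, grid)
  tf0 <- sample_traction_forces(mask, grid, n_forces = 0, prior = pr)
  expect_true(all(tf0$fx == 0 & tf0$fy == 0))
  tf <- sample_traction_forces(mask, grid, n_forces = 15,
                               direction_noise_sd = 0, prior = pr, seed = 2)
  on <- tf$fx != 0 | tf$fy != 0
  expect_identical(sum(on), 15L)
  expect_true(all(tf$inside_cell[on]))
  # with no angular noise on a disk, forces aim at the center
  cx <- (64 - 1) / 2 * 0.5
  dot <- tf$fx[on] * (cx - tf$x_um[on]) + tf$fy[on] * (cx - tf$y_um[on])
  nrm <- sqrt(tf$fx[on]^2 + tf$fy[on]^2) *
    sqrt((cx - tf$x_um[on])^2 + (cx - tf$y_um[on])^2)
  ang <- acos(pmin(pmax(dot / nrm, -1), 1))
  expect_lt(max(ang), 3 * pi / 180)
  expect_error(sample_traction_forces(mask, grid, n_forces = 1000,
                                      prior = pr), "eligible")
})

test_that("bead scatter has the right count, determinism, and uniform spacing", {
  mask <- generate_boundary("circle", dim = c(50, 50), pixel_size = 0.2,
                            size = 3)
  grid <- force_grid(mask, 10, 10)
  ext <- attr(grid, "field_extent")
  b <- scatter_beads(grid, density = 0.4, seed = 1)
  expect_identical(nrow(b), as.integer(round(0.4 * ext[["width"]] *
                                               ext[["height"]])))
  expect_identical(scatter_beads(grid, 0.4, seed = 1), b)
  expect_false(identical(scatter_beads(grid, 0.4, seed = 2)$x_um, b$x_um))
  # nearest-neighbour distances agree with a direct uniform sample (KS test)
  big <- scatter_beads(grid, density = 5, seed = 3)  # n = 500
  nn <- function(x, y) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    apply(d, 1, min)
  }
  ref <- withr::with_seed(4, list(
    x = stats::runif(nrow(big), min(grid$x_um), max(grid$x_um)),
    y = stats::runif(nrow(big), min(grid$y_um), max(grid$y_um))))
  ks <- suppressWarnings(stats::ks.test(nn(big$x_um, big$y_um),
                                        nn(ref$x, ref$y)))
  expect_gt(ks$p.value, 0.01)
})

test_that("datasets chain the forward model and are seed-reproducible", {
  cfg <- tiny_config(noise_sd = 0)
  ds <- make_dataset(cfg, seed = 3)
  u <- interleave_xy(ds$beads$ux_um, ds$beads$uy_um)
  expect_identical(u, ds$clean_displacements)
  ds_n <- make_dataset(tiny_config(noise_sd = 0.1), seed = 3)
  u_n <- interleave_xy(ds_n$beads$ux_um, ds_n$beads$uy_um)
  expect_false(identical(u_n, ds_n$clean_displacements))
  expect_equal(sd(u_n - ds_n$clean_displacements), 0.1, tolerance = 0.2)
  # bit-exact reproducibility from the master seed
  ds2 <- make_dataset(cfg, seed = 3)
  expect_identical(ds$beads, ds2$beads)
  expect_identical(ds$true_forces, ds2$true_forces)
  expect_identical(ds$mask$raster, ds2$mask$raster)
  # zero forces give zero displacements
  ds0 <- make_dataset(tiny_config(n_forces = 0, noise_sd = 0), seed = 1)
  expect_true(all(ds0$clean_displacements == 0))
})

test_that("a single distant force matches the scalar kernel evaluation", {
  sys <- toy_system(seed = 30, n_beads = 1, rows = 4, cols = 4)
  G <- assemble_greens_matrix(sys$beads, sys$grid, sys$substrate)
  f <- rep(0, 32)
  f[9] <- 2.5  # x component of grid point 5
  f[10] <- -1
  u <- forward_displacements(G, f)
  blk <- (attr(sys$grid, "cell_area") / 16) * greens_tensor(
    c(sys$beads$x_um[1] - sys$grid$x_um[5],
      sys$beads$y_um[1] - sys$grid$y_um[5]), sys$substrate)
  expect_equal(u, drop(blk %*% c(2.5, -1)), tolerance = 1e-12)
})

test_that("bead displacements decay away from the force set", {
  ds <- tiny_dataset(seed = 2)
  um <- sqrt(ds$beads$ux_um^2 + ds$beads$uy_um^2)
  expect_gt(max(um), stats::median(um))
})
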