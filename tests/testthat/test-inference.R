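rot <- function(theta) matrix(c(cos(theta), sin(theta),
                                -sin(theta), cos(theta)), 2, 2)

test_that("local correction rotates then scales the prior center", {
  f <- c(1.2, -0.4)
  expect_equal(apply_local_correction(f, 0, 1), f)
  expect_equal(apply_local_correction(f, pi, 1), -f)
  expect_equal(apply_local_correction(c(1, 0), pi / 2, 2), c(0, 2))
  # matrix form agrees with per-row application
  M <- rbind(c(1, 0), c(0.3, -0.7))
  th <- c(0.4, -1.1)
  s <- c(2, 0.5)
  out <- apply_local_correction(M, th, s)
  for (i in 1:2)
    expect_equal(out[i, ], apply_local_correction(M[i, ], th[i], s[i]))
})

test_that("log posterior matches a scalar-loop evaluation", {
  hp <- btfe_hyperparams(alpha = 1.3, beta = 0.2)
  withr::with_seed(8, {
    G <- matrix(rnorm(8), 2, 4)
    f <- rnorm(4)
    u <- rnorm(2)
    Fm <- rnorm(4)
  })
  # independent scalar-loop oracle
  acc_u <- 0
  for (i in 1:2) {
    gi <- 0
    for (j in 1:4) gi <- gi + G[i, j] * f[j]
    acc_u <- acc_u + (u[i] - gi)^2
  }
  acc_f <- 0
  for (j in 1:4) acc_f <- acc_f + (f[j] - Fm[j])^2
  expect_equal(log_posterior(f, u, G, Fm, hp),
               -1.3 / 2 * acc_u - 0.2 / 2 * acc_f)
  # both residuals vanishing gives 0
  expect_equal(log_posterior(Fm, drop(G %*% Fm), G, Fm, hp), 0)
  expect_error(log_posterior(f[-1], u, G, Fm, hp), "dimension")
})

test_that("closed-form MAP force maximizes the objective (grid-search oracle)", {
  hp <- btfe_hyperparams(alpha = 1, beta = 0.1)
  withr::with_seed(21, {
    G <- matrix(rnorm(4), 2, 2)
    u <- rnorm(2)
    Fm <- rnorm(2)
  })
  f_star <- map_force_given_corrections(u, G, Fm, hp)
  J <- function(f) log_posterior(f, u, G, Fm, hp)
  offsets <- expand.grid(dx = seq(-0.5, 0.5, by = 0.05),
                         dy = seq(-0.5, 0.5, by = 0.05))
  vals <- apply(offsets, 1, function(o) J(f_star + as.numeric(o)))
  expect_true(all(vals <= J(f_star) + 1e-12))
})

test_that("MAP force approaches the prior (large beta) and the inverse (small beta)", {
  withr::with_seed(31, {
    G <- matrix(rnorm(16), 4, 4) + 4 * diag(4)  # well conditioned
    u <- rnorm(4)
    Fm <- rnorm(4)
  })
  f_prior <- map_force_given_corrections(u, G, Fm, btfe_hyperparams(beta = 1e8))
  expect_equal(f_prior, Fm, tolerance = 1e-5)
  f_lik <- map_force_given_corrections(u, G, Fm, btfe_hyperparams(beta = 1e-10))
  expect_equal(f_lik, solve(G, u), tolerance = 1e-5)
})

test_that("correction update solves the per-point penalized problem", {
  hp <- btfe_hyperparams(beta = 0.1, gamma = 1e-6)
  fmu <- c(0.8, 0.3)
  # trivial identities
  id <- update_corrections(fmu, fmu, hp)
  expect_equal(id$theta, 0)
  expect_equal(id$s, 1, tolerance = 1e-4)
  z <- update_corrections(c(0, 0), fmu, hp)
  expect_equal(z$s, 0)
  nz <- update_corrections(c(1, 1), c(0, 0), hp)
  expect_equal(nz$s, 0)
  expect_equal(nz$theta, 0)
  # rotated + scaled prior center recovered, vs 2D grid-search oracle
  f <- 2 * drop(rot(0.3) %*% fmu)
  up <- update_corrections(f, fmu, hp)
  expect_equal(up$theta, 0.3, tolerance = 1e-9)
  expect_equal(up$s, 2, tolerance = 1e-3)
  obj <- function(theta, s) {
    r <- f - apply_local_correction(fmu, theta, s)
    -hp$beta / 2 * sum(r^2) - hp$gamma * abs(s)
  }
  gr <- expand.grid(theta = seq(-pi, pi, by = 0.005),
                    s = seq(0, 4, by = 0.005))
  best <- max(mapply(obj, gr$theta, gr$s))
  expect_gte(obj(up$theta, up$s), best - 1e-9)
})

test_that("soft threshold zeroes weak corrections", {
  hp <- btfe_hyperparams(beta = 0.1, gamma = 0.01)
  fmu <- c(0.1, 0)  # threshold gamma/(beta |fmu|^2) = 10
  up <- update_corrections(c(0.5, 0), fmu, hp)  # raw s = 5 < 10
  expect_equal(up$s, 0)
  up2 <- update_corrections(c(2, 0), fmu, hp)   # raw s = 20 -> 20 - 10
  expect_equal(up2$s, 10)
})

test_that("EM recovers forces exactly when data come from the prior center", {
  sys <- toy_system(seed = 13, n_beads = 30, dim = 48, rows = 10, cols = 10)
  pr <- boundary_prior(sys$mask, sys$grid)
  prior_raw <- interleave_xy(pr$fmux, pr$fmuy)
  G <- assemble_greens_matrix(sys$beads, sys$grid, sys$substrate)
  u <- drop(G %*% prior_raw)
  hp <- btfe_hyperparams(gamma = 1e-12)
  est <- em_estimate(u, G, prior_raw, hp, n_restarts = 1, seed = 1)
  expect_lt(sqrt(sum((est$f - prior_raw)^2)) / sqrt(sum(prior_raw^2)), 0.01)
  # objective at the estimate is at least the objective at the truth
  corr_truth <- update_corrections(prior_raw, prior_raw, hp)
  Fm_truth <- as.vector(t(apply_local_correction(
    cbind(pr$fmux, pr$fmuy), corr_truth$theta, corr_truth$s)))
  obj_truth <- log_posterior(prior_raw, u, G, Fm_truth, hp) -
    hp$gamma * sum(abs(corr_truth$s))
  expect_gte(est$log_map, obj_truth - 1e-9)
})

test_that("EM objective is non-decreasing within every restart", {
  sys <- toy_system(seed = 17, n_beads = 25, dim = 48, rows = 8, cols = 8)
  pr <- boundary_prior(sys$mask, sys$grid)
  prior_raw <- interleave_xy(pr$fmux, pr$fmuy)
  G <- assemble_greens_matrix(sys$beads, sys$grid, sys$substrate)
  withr::with_seed(2, u <- drop(G %*% prior_raw) + rnorm(50, 0, 0.1))
  est <- em_estimate(u, G, prior_raw, btfe_hyperparams(), n_restarts = 3,
                     seed = 5)
  expect_true(all(diff(est$objective_trace) >= -1e-9))
  expect_true(est$converged)
})

test_that("EM with a null prior equals ridge regression with penalty beta/alpha", {
  sys <- toy_system(seed = 23, n_beads = 20, dim = 48, rows = 6, cols = 6)
  G <- assemble_greens_matrix(sys$beads, sys$grid, sys$substrate)
  withr::with_seed(3, u <- rnorm(40, 0, 0.3))
  for (hp in list(btfe_hyperparams(alpha = 1, beta = 0.1),
                  btfe_hyperparams(alpha = 2, beta = 0.5))) {
    est <- em_estimate(u, G, rep(0, ncol(G)), hp, n_restarts = 2, seed = 1)
    lam <- hp$beta / hp$alpha
    f_ridge <- solve(crossprod(G) + lam * diag(ncol(G)), crossprod(G, u))
    expect_equal(est$f, drop(f_ridge), tolerance = 1e-8)
  }
})

test_that("a fixed seed reproduces the posterior estimate bit-exactly", {
  ds <- tiny_dataset(seed = 4)
  f1 <- btfe(ds$beads, ds$mask, substrate = ds$substrate, grid = ds$grid,
             prior = ds$prior, n_restarts = 3, seed = 11)
  f2 <- btfe(ds$beads, ds$mask, substrate = ds$substrate, grid = ds$grid,
             prior = ds$prior, n_restarts = 3, seed = 11)
  expect_identical(f1$forces, f2$forces)
  expect_identical(f1$log_map, f2$log_map)
})

test_that("the Bayesian estimate beats prior-only and ridge in its own objective", {
  ds <- tiny_dataset(seed = 0)
  hp <- btfe_hyperparams()
  fit <- btfe(ds$beads, ds$mask, substrate = ds$substrate, grid = ds$grid,
              prior = ds$prior, seed = 0)
  G <- assemble_greens_matrix(ds$beads, ds$grid, ds$substrate)
  u <- interleave_xy(ds$beads$ux_um, ds$beads$uy_um)
  prior_raw <- fit$prior_scale * interleave_xy(ds$prior$fmux, ds$prior$fmuy)
  prior_mat <- fit$prior_scale * cbind(ds$prior$fmux, ds$prior$fmuy)
  penalized <- function(f) {
    corr <- update_corrections(f, prior_raw, hp)
    Fm <- as.vector(t(apply_local_correction(prior_mat, corr$theta, corr$s)))
    log_posterior(f, u, G, Fm, hp) - hp$gamma * sum(abs(corr$s))
  }
  ridge_fit <- tfm_baseline(ds$beads, ds$mask, method = "ridge",
                            substrate = ds$substrate, grid = ds$grid,
                            seed = 0)
  f_btfe <- interleave_xy(fit$forces$fx, fit$forces$fy)
  f_ridge <- interleave_xy(ridge_fit$forces$fx, ridge_fit$forces$fy)
  expect_gt(penalized(f_btfe), penalized(prior_raw))
  expect_gt(penalized(f_btfe), penalized(f_ridge))
})

test_that("force directions are recovered at true force points (dense beads)", {
  cfg <- tfm_config(field_px = 64, bead_density = 1.6)
  ds <- make_dataset(cfg, seed = 6)
  fit <- btfe(ds$beads, ds$mask, substrate = ds$substrate, grid = ds$grid,
              prior = ds$prior, seed = 6)
  pos <- which(ds$true_forces$fx != 0 | ds$true_forces$fy != 0)
  tf <- ds$true_forces[pos, ]
  ef <- fit$forces[pos, ]
  dot <- tf$fx * ef$fx + tf$fy * ef$fy
  nrm <- sqrt(tf$fx^2 + tf$fy^2) * sqrt(ef$fx^2 + ef$fy^2)
  ang <- acos(pmin(pmax(dot / pmax(nrm, 1e-12), -1), 1))
  expect_lt(stats::median(ang), 30 * pi / 180)
})
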