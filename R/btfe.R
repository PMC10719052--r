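#' Hyperparameters of the Bayesian traction force model
#'
#' @param alpha likelihood precision weight (default 1).
#' @param beta prior precision weight on the force deviation from its
#'   corrected center (default 0.1: the prior gets roughly 10% of the
#'   likelihood's weight).
#' @param gamma reciprocal scale of the Laplace prior on the per-point
#'   magnitude corrections s (default 0.01); drives unneeded corrections to
#'   exactly zero, like a lasso penalty.
#' @param sigma2_fraction magnitude-decay sigma^2 as a fraction of cell
#'   area (default 0.1).
#' @return An object of class `btfe_hyperparams`.
#' @export
btfe_hyperparams <- function(alpha = 1, beta = 0.1, gamma = 0.01,
                             sigma2_fraction = 0.1) {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma,
            sigma2_fraction = sigma2_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hyperparameters must be positive and finite", call. = FALSE)
  structure(as.list(vals), class = "btfe_hyperparams")
}

#' Rotate and scale a prior center vector
#'
#' f_n = s R(theta) f_mu: the per-point local correction applied to the
#' prior center, a rotation by `theta` followed by scaling with `s`.
#'
#' @param f_mu length-2 vector or 2-column matrix (rows = points).
#' @param theta rotation angle(s), radians.
#' @param s scale factor(s).
#' @return Corrected vector(s), same shape as `f_mu`.
#' @export
apply_local_correction <- function(f_mu, theta, s) {
  if (is.matrix(f_mu)) {
    cbind(s * (cos(theta) * f_mu[, 1] - sin(theta) * f_mu[, 2]),
          s * (sin(theta) * f_mu[, 1] + cos(theta) * f_mu[, 2]))
  } else {
    stopifnot(length(f_mu) == 2)
    s * c(cos(theta) * f_mu[1] - sin(theta) * f_mu[2],
          sin(theta) * f_mu[1] + cos(theta) * f_mu[2])
  }
}

#' Log posterior density of a force field (up to a constant)
#'
#' -(alpha/2) ||u_obs - G f||^2 - (beta/2) ||f - F_mu||^2, the operative
#' MAP objective given corrected prior centers F_mu.
#'
#' @param f stacked force vector (2N).
#' @param u_obs stacked observed displacement vector (2B).
#' @param G Green's matrix (2B x 2N).
#' @param F_mu corrected prior center vector (2N).
#' @param hp a [btfe_hyperparams()].
#' @return scalar log density (constants dropped).
#' @export
log_posterior <- function(f, u_obs, G, F_mu, hp) {
  stopifnot(inherits(hp, "btfe_hyperparams"))
  if (length(f) != ncol(G) || length(u_obs) != nrow(G) ||
      length(F_mu) != length(f))
    stop("dimension mismatch in log_posterior", call. = FALSE)
  res_u <- u_obs - drop(G %*% f)
  res_f <- f - F_mu
  -hp$alpha / 2 * sum(res_u^2) - hp$beta / 2 * sum(res_f^2)
}

#' Closed-form MAP force field given fixed corrections
#'
#' The objective is quadratic in f; the unique maximizer is
#' f* = (alpha G'G + beta I)^(-1) (alpha G' u_obs + beta F_mu), computed via
#' a Cholesky factorization (never an explicit inverse).
#'
#' @inheritParams log_posterior
#' @param chol_fac optional precomputed `chol(alpha G'G + beta I)` (upper
#'   triangular), reused across EM iterations.
#' @param Gtu optional precomputed `alpha * crossprod(G, u_obs)`.
#' @return stacked MAP force vector (2N).
#' @export
map_force_given_corrections <- function(u_obs, G, F_mu, hp,
                                        chol_fac = NULL, Gtu = NULL) {
  stopifnot(inherits(hp, "btfe_hyperparams"))
  if (is.null(chol_fac)) {
    M <- hp$alpha * crossprod(G)
    diag(M) <- diag(M) + hp$beta
    chol_fac <- chol(M)
  }
  if (is.null(Gtu)) Gtu <- hp$alpha * crossprod(G, u_obs)
  rhs <- Gtu + hp$beta * F_mu
  drop(backsolve(chol_fac, backsolve(chol_fac, rhs, transpose = TRUE)))
}

#' Exact per-point update of the local corrections
#'
#' For each grid point, maximizes
#' -(beta/2) ||f_n - s R(theta) f_mu_n||^2 - gamma |s| over (theta, s):
#' theta aligns the rotated prior center with the current force estimate
#' (theta_n = angle(f_n) - angle(f_mu_n), wrapped to (-pi, pi]), and s is
#' the 1D Laplace-penalized least-squares solution given theta_n, i.e. the
#' soft-thresholding of |f_n|/|f_mu_n| at gamma / (beta |f_mu_n|^2).
#' Points with a zero prior center (or zero force) get s = 0, theta = 0.
#'
#' @param f stacked force vector (2N).
#' @param prior_raw stacked uncorrected prior center vector (2N).
#' @param hp a [btfe_hyperparams()].
#' @return list(theta, s), numeric vectors of length N.
#' @export
update_corrections <- function(f, prior_raw, hp) {
  stopifnot(inherits(hp, "btfe_hyperparams"),
            length(f) == length(prior_raw), all(is.finite(f)))
  fc <- split_xy(f)
  mc <- split_xy(prior_raw)
  f_norm <- sqrt(fc$x^2 + fc$y^2)
  mu_norm2 <- mc$x^2 + mc$y^2
  ok <- mu_norm2 > 0 & f_norm > 0
  theta <- rep(0, length(f_norm))
  s <- rep(0, length(f_norm))
  theta[ok] <- wrap_angle(atan2(fc$y[ok], fc$x[ok]) -
                          atan2(mc$y[ok], mc$x[ok]))
  s_raw <- f_norm[ok] / sqrt(mu_norm2[ok])
  thr <- hp$gamma / (hp$beta * mu_norm2[ok])
  s[ok] <- pmax(s_raw - thr, 0)
  list(theta = theta, s = s)
}

#' @keywords internal penalized joint objective of the coordinate ascent
#' @noRd
em_objective <- function(f, u_obs, G, F_mu, s, hp) {
  log_posterior(f, u_obs, G, F_mu, hp) - hp$gamma * sum(abs(s))
}

#' MAP estimation with EM-style optimization of local corrections
#'
#' Alternates the closed-form force update ([map_force_given_corrections()])
#' with the exact per-point correction update ([update_corrections()]),
#' which is coordinate ascent on the penalized log posterior
#' J(f, theta, s) = -(alpha/2)||u - G f||^2 - (beta/2)||f - F_mu(theta,s)||^2
#' - gamma sum|s_n|, so J is non-decreasing across iterations. Because the
#' objective is non-concave jointly, several restarts are run: restart 0
#' starts from the unmodified prior (s = 1, theta = 0), the others from
#' randomized corrections (s ~ |N(1, 0.5^2)|, theta ~ U(-pi/4, pi/4)); the
#' restart with the highest final objective wins.
#'
#' @param u_obs stacked observed displacements (2B).
#' @param G Green's matrix (2B x 2N).
#' @param prior_raw stacked uncorrected prior center (2N).
#' @param hp a [btfe_hyperparams()].
#' @param n_restarts number of initializations (default 5).
#' @param seed integer seed for the randomized restarts.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @return list with `f` (2N MAP forces), `theta`, `s`, `log_map` (penalized
#'   objective at the optimum), `objective_trace`, `n_restarts_used`,
#'   `converged`, `restart_objectives`.
#' @export
em_estimate <- function(u_obs, G, prior_raw, hp, n_restarts = 5, seed = NULL,
                        tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(hp, "btfe_hyperparams"))
  N <- ncol(G) / 2
  M <- hp$alpha * crossprod(G)
  diag(M) <- diag(M) + hp$beta
  chol_fac <- chol(M)
  Gtu <- hp$alpha * crossprod(G, u_obs)
  prior_mat <- do.call(cbind, split_xy(prior_raw))
  if (is.null(seed)) seed <- 0L
  restart_seeds <- derive_seeds(seed, max(n_restarts, 1))

  run_restart <- function(r) {
    if (r == 1) {
      theta <- rep(0, N)
      s <- rep(1, N)
    } else {
      init <- withr::with_seed(restart_seeds[r], list(
        s = abs(stats::rnorm(N, 1, 0.5)),
        theta = stats::runif(N, -pi / 4, pi / 4)))
      theta <- init$theta
      s <- init$s
    }
    obj_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    f <- NULL
    for (it in seq_len(max_iter)) {
      F_mu <- as.vector(t(apply_local_correction(prior_mat, theta, s)))
      f <- map_force_given_corrections(u_obs, G, F_mu, hp,
                                       chol_fac = chol_fac, Gtu = Gtu)
      corr <- update_corrections(f, prior_raw, hp)
      theta <- corr$theta
      s <- corr$s
      F_mu2 <- as.vector(t(apply_local_correction(prior_mat, theta, s)))
      obj <- em_objective(f, u_obs, G, F_mu2, s, hp)
      if (!is.finite(obj)) return(NULL)
      if (obj < obj_prev - 1e-8 * (1 + abs(obj_prev)))
        stop("internal error: coordinate-ascent objective decreased",
             call. = FALSE)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          abs(obj - obj_prev) < tol * (1 + abs(obj_prev))) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    list(f = f, theta = theta, s = s, log_map = trace[length(trace)],
         trace = trace, converged = converged)
  }

  results <- lapply(seq_len(max(n_restarts, 1)), run_restart)
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all EM restarts diverged", call. = FALSE)
  objs <- vapply(results, function(r) if (is.null(r)) -Inf else r$log_map,
                 numeric(1))
  best <- results[[which.max(objs)]]
  list(f = best$f, theta = best$theta, s = best$s,
       log_map = best$log_map, objective_trace = best$trace,
       n_restarts_used = sum(ok), converged = best$converged,
       restart_objectives = objs)
}

#' Bayesian traction force estimation from beads and a cell mask
#'
#' High-level pipeline: force grid over the image field, boundary-dependent
#' prior (magnitude decay + MCF inward directions), Green's matrix, and
#' MAP/EM estimation of forces with per-point corrections.
#'
#' @param beads bead tibble with columns `x_um`, `y_um`, `ux_um`, `uy_um`.
#' @param mask a [cell_mask()].
#' @param substrate an [elastic_substrate()].
#' @param grid optional [force_grid()]; default 30 x 30 over the mask field.
#' @param hp a [btfe_hyperparams()].
#' @param prior optional precomputed [boundary_prior()] tibble on `grid`.
#' @param tau MCF time (pixel^2); default [default_mcf_tau()].
#' @param prior_scale global prior center scale: the typical traction
#'   magnitude of the cell type, in the same force units as the Green's
#'   matrix. Default 1, i.e. forces measured in units of the typical
#'   traction. Like the cell boundary itself, this is prior biological
#'   knowledge: the Laplace penalty on the per-point magnitude corrections
#'   is not invariant to the force unit, so a grossly mis-scaled prior
#'   center would switch the boundary prior off (far too small) or swamp
#'   the data (far too large).
#' @param n_restarts,seed,tol,max_iter EM controls, see [em_estimate()].
#' @return An object of class `btfe_fit`: forces tibble (grid columns plus
#'   `fx`, `fy`, `theta`, `s`), `log_map`, diagnostics, inputs.
#' @examples
#' \donttest{
#' ds <- make_dataset(tfm_config(shape = "blob", bead_density = 0.4), seed = 1)
#' fit <- btfe(ds$beads, ds$mask, seed = 1)
#' glance(fit)
#' }
#' @export
btfe <- function(beads, mask, substrate = elastic_substrate(),
                 grid = NULL, hp = btfe_hyperparams(), prior = NULL,
                 tau = default_mcf_tau(mask), prior_scale = 1,
                 n_restarts = 5, seed = NULL, tol = 1e-6, max_iter = 200) {
  stopifnot(is.numeric(prior_scale), prior_scale > 0)
  if (is.null(grid)) grid <- force_grid(mask)
  if (is.null(prior))
    prior <- boundary_prior(mask, grid, tau = tau,
                            sigma2_fraction = hp$sigma2_fraction,
                            scale = 1)
  G <- assemble_greens_matrix(beads, grid, substrate)
  u_obs <- interleave_xy(beads$ux_um, beads$uy_um)
  prior_raw <- prior_scale * interleave_xy(prior$fmux, prior$fmuy)
  est <- em_estimate(u_obs, G, prior_raw, hp, n_restarts = n_restarts,
                     seed = seed, tol = tol, max_iter = max_iter)
  fxy <- split_xy(est$f)
  forces <- grid
  forces$fx <- fxy$x
  forces$fy <- fxy$y
  forces$theta <- est$theta
  forces$s <- est$s
  structure(list(forces = forces, log_map = est$log_map,
                 corrections = list(theta = est$theta, s = est$s),
                 objective_trace = est$objective_trace,
                 restart_objectives = est$restart_objectives,
                 n_restarts_used = est$n_restarts_used,
                 converged = est$converged,
                 hyperparams = hp, prior = prior, prior_scale = prior_scale,
                 mask = mask,
                 substrate = substrate, seed = seed, method = "btfe"),
            class = "btfe_fit")
}

#' @export
print.btfe_fit <- function(x, ...) {
  cat(sprintf(
    "<btfe_fit> %d force points, log MAP objective %.4g, %s (%d restarts)\n",
    nrow(x$forces), x$log_map,
    if (x$converged) "converged" else "iteration cap reached",
    x$n_restarts_used))
  invisible(x)
}
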