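#' Default regularization grid for the baselines
#'
#' Logarithmic grid, 25 points over 1e-4 ... 1e2.
#' @return decreasing numeric vector of penalties.
#' @export
default_lambda_grid <- function() {
  sort(10^seq(-4, 2, length.out = 25), decreasing = TRUE)
}

#' @keywords internal bead-wise k-fold assignment (both components together)
#' @noRd
bead_folds <- function(B, k_folds, seed = NULL) {
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  if (k_folds > B)
    stop(sprintf("cannot split %d beads into %d folds", B, k_folds),
         call. = FALSE)
  fold_of_bead <- if (is.null(seed)) {
    sample(rep_len(seq_len(k_folds), B))
  } else {
    withr::with_seed(seed, sample(rep_len(seq_len(k_folds), B)))
  }
  # expand to interleaved row indices (x and y rows of a bead share a fold)
  rep(fold_of_bead, each = 2)
}

#' @keywords internal ridge path via SVD: f(lambda) = V d/(d^2+lambda) U'u
#' @noRd
ridge_path <- function(G, u, lambdas) {
  sv <- svd(G)
  utu <- drop(crossprod(sv$u, u))
  sapply(lambdas, function(l) {
    drop(sv$v %*% (sv$d / (sv$d^2 + l) * utu))
  })
}

#' Ridge traction estimation with bead-wise cross-validation
#'
#' Solves f = argmin ||u - G f||^2 + lambda ||f||^2 at the lambda that
#' minimizes k-fold cross-validated prediction error. Folds are split by
#' bead, so the x and y displacement components of one bead always land in
#' the same fold. Magnitude regularization spreads small forces widely and
#' shrinks everything toward zero as lambda grows.
#'
#' @param u_obs stacked observed displacements (2B).
#' @param G Green's matrix (2B x 2N).
#' @param lambda_grid candidate penalties (default [default_lambda_grid()]).
#' @param k_folds number of CV folds (default 5).
#' @param seed integer seed for the fold split.
#' @return An object of class `baseline_fit`: `f` (2N), `lambda`, `cv_curve`
#'   tibble (lambda, cv_error), `method = "ridge"`.
#' @export
ridge_estimate <- function(u_obs, G, lambda_grid = default_lambda_grid(),
                           k_folds = 5, seed = NULL) {
  B <- nrow(G) / 2
  lambdas <- sort(lambda_grid, decreasing = TRUE)
  folds <- bead_folds(B, k_folds, seed)
  sse <- matrix(0, length(lambdas), k_folds)
  for (k in seq_len(k_folds)) {
    test <- folds == k
    if (!any(test) || all(test))
      stop("degenerate cross-validation fold", call. = FALSE)
    path <- ridge_path(G[!test, , drop = FALSE], u_obs[!test], lambdas)
    pred <- G[test, , drop = FALSE] %*% path
    sse[, k] <- colSums((pred - u_obs[test])^2)
  }
  cv_err <- rowSums(sse) / (2 * B)
  best <- which.min(cv_err)
  f <- drop(ridge_path(G, u_obs, lambdas[best]))
  structure(list(f = f, lambda = lambdas[best],
                 cv_curve = tibble::tibble(lambda = lambdas,
                                           cv_error = cv_err),
                 method = "ridge"),
            class = "baseline_fit")
}

#' Lasso traction estimation with bead-wise cross-validation
#'
#' Solves f = argmin (1/2) ||u - G f||^2 + lambda ||f||_1 (penalty on each
#' scalar force component) at the CV-optimal lambda, via glmnet without
#' intercept or standardization (glmnet's lambda is the penalty here divided
#' by the number of displacement rows). The L1 penalty yields sparse force
#' maps: few, large forces.
#'
#' @inheritParams ridge_estimate
#' @param thresh glmnet convergence threshold.
#' @return An object of class `baseline_fit` with `method = "lasso"`.
#' @export
lasso_estimate <- function(u_obs, G, lambda_grid = default_lambda_grid(),
                           k_folds = 5, seed = NULL, thresh = 1e-7) {
  B <- nrow(G) / 2
  lambdas <- sort(lambda_grid, decreasing = TRUE)
  folds <- bead_folds(B, k_folds, seed)
  sse <- matrix(0, length(lambdas), k_folds)
  for (k in seq_len(k_folds)) {
    test <- folds == k
    if (!any(test) || all(test))
      stop("degenerate cross-validation fold", call. = FALSE)
    n_train <- sum(!test)
    fit <- glmnet::glmnet(G[!test, , drop = FALSE], u_obs[!test],
                          alpha = 1, lambda = lambdas / n_train,
                          intercept = FALSE, standardize = FALSE,
                          thresh = thresh)
    coefs <- as.matrix(fit$beta)
    if (ncol(coefs) != length(lambdas))
      stop("lasso solver did not return the full regularization path",
           call. = FALSE)
    pred <- G[test, , drop = FALSE] %*% coefs
    sse[, k] <- colSums((pred - u_obs[test])^2)
  }
  cv_err <- rowSums(sse) / (2 * B)
  best <- which.min(cv_err)
  n_all <- 2 * B
  fit_all <- glmnet::glmnet(G, u_obs, alpha = 1, lambda = lambdas / n_all,
                            intercept = FALSE, standardize = FALSE,
                            thresh = thresh)
  f <- as.numeric(fit_all$beta[, best])
  structure(list(f = f, lambda = lambdas[best],
                 cv_curve = tibble::tibble(lambda = lambdas,
                                           cv_error = cv_err),
                 method = "lasso"),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %s, lambda = %.4g, %d nonzero of %d components\n",
              x$method, x$lambda, sum(x$f != 0), length(x$f)))
  invisible(x)
}

#' Ridge or lasso traction estimation from beads and a mask
#'
#' Baseline counterpart of [btfe()]: assembles the same forward model and
#' runs regularized regression with bead-wise cross-validation.
#'
#' @inheritParams btfe
#' @param method `"ridge"` or `"lasso"`.
#' @param lambda_grid,k_folds CV controls.
#' @return A `baseline_fit` whose `forces` element is the grid tibble with
#'   `fx`, `fy` columns.
#' @export
tfm_baseline <- function(beads, mask, method = c("ridge", "lasso"),
                         substrate = elastic_substrate(), grid = NULL,
                         lambda_grid = default_lambda_grid(), k_folds = 5,
                         seed = NULL) {
  method <- match.arg(method)
  if (is.null(grid)) grid <- force_grid(mask)
  G <- assemble_greens_matrix(beads, grid, substrate)
  u_obs <- interleave_xy(beads$ux_um, beads$uy_um)
  fit <- switch(method,
    ridge = ridge_estimate(u_obs, G, lambda_grid, k_folds, seed),
    lasso = lasso_estimate(u_obs, G, lambda_grid, k_folds, seed))
  fxy <- split_xy(fit$f)
  forces <- grid
  forces$fx <- fxy$x
  forces$fy <- fxy$y
  fit$forces <- forces
  fit$mask <- mask
  fit$seed <- seed
  fit
}
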