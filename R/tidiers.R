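#' Tidy a Bayesian traction force fit
#'
#' One row per force grid point with the estimated force components, its
#' magnitude, and the learned local corrections.
#'
#' @param x a `btfe_fit`.
#' @param ... unused.
#' @return tibble: grid columns, `fx`, `fy`, `magnitude`, `theta`, `s`.
#' @export
tidy.btfe_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$forces)
  out$magnitude <- sqrt(out$fx^2 + out$fy^2)
  out
}

#' One-row summary of a Bayesian traction force fit
#'
#' @param x a `btfe_fit`.
#' @param ... unused.
#' @return tibble with the MAP objective, convergence flag, restart count,
#'   numbers of active corrections and force points.
#' @export
glance.btfe_fit <- function(x, ...) {
  tibble::tibble(
    log_map = x$log_map,
    converged = x$converged,
    n_restarts_used = x$n_restarts_used,
    n_iter = length(x$objective_trace),
    n_active_s = sum(x$corrections$s != 0),
    n_grid = nrow(x$forces),
    alpha = x$hyperparams$alpha,
    beta = x$hyperparams$beta,
    gamma = x$hyperparams$gamma)
}

#' Tidy a ridge/lasso baseline fit
#'
#' @param x a `baseline_fit` from [tfm_baseline()].
#' @param ... unused.
#' @return tibble: grid columns, `fx`, `fy`, `magnitude`.
#' @export
tidy.baseline_fit <- function(x, ...) {
  if (is.null(x$forces))
    stop("this baseline_fit has no grid attached; use tfm_baseline()",
         call. = FALSE)
  out <- tibble::as_tibble(x$forces)
  out$magnitude <- sqrt(out$fx^2 + out$fy^2)
  out
}

#' One-row summary of a baseline fit
#'
#' @param x a `baseline_fit`.
#' @param ... unused.
#' @return tibble with method, selected lambda, CV error at the optimum,
#'   and sparsity.
#' @export
glance.baseline_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    lambda = x$lambda,
    cv_error = x$cv_curve$cv_error[x$cv_curve$lambda == x$lambda][1],
    n_nonzero = sum(x$f != 0),
    n_components = length(x$f))
}
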