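#' @keywords internal magnitude per grid point of a force-field tibble
#' @noRd
force_magnitudes <- function(field) {
  sqrt(field$fx^2 + field$fy^2)
}

#' @keywords internal check two fields share a grid
#' @noRd
check_same_grid <- function(est, truth) {
  if (nrow(est) != nrow(truth) ||
      any(est$grid_i != truth$grid_i) || any(est$grid_j != truth$grid_j))
    stop("estimated and true force fields are on different grids",
         call. = FALSE)
}

#' ROC curve and AUC of force detection
#'
#' Grid points where the generator placed a force are positives; all other
#' grid points inside the cell are negatives (estimation accuracy is always
#' assessed in the cellular region only). The estimated force magnitude is
#' swept through every distinct threshold to build the ROC curve; the AUC
#' equals the Mann-Whitney statistic with 0.5 credit for ties, so it is
#' invariant under any strictly monotone transform of the magnitudes.
#'
#' @param est estimated force-field tibble (grid columns plus `fx`, `fy`).
#' @param truth true force-field tibble on the same grid.
#' @param region logical vector of evaluation-region membership per grid
#'   point; default the grid's `inside_cell`.
#' @return list: `auc`, `roc` (tibble threshold/tpr/fpr), `m_pos`, `m_neg`.
#' @export
roc_auc <- function(est, truth, region = NULL) {
  check_same_grid(est, truth)
  if (is.null(region)) region <- truth$inside_cell
  pos_all <- force_magnitudes(truth) > 0
  scores <- force_magnitudes(est)[region]
  labels <- pos_all[region]
  m_pos <- sum(labels)
  m_neg <- sum(!labels)
  if (m_pos == 0 || m_neg == 0)
    stop("evaluation region must contain at least one positive and one negative point",
         call. = FALSE)
  rk <- rank(scores)  # midranks: ties get 0.5 credit
  auc <- (sum(rk[labels]) - m_pos * (m_pos + 1) / 2) / (m_pos * m_neg)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, thresholds),
    tpr = vapply(c(Inf, thresholds),
                 function(t) mean(scores[labels] >= t), numeric(1)),
    fpr = vapply(c(Inf, thresholds),
                 function(t) mean(scores[!labels] >= t), numeric(1)))
  list(auc = auc, roc = roc, m_pos = m_pos, m_neg = m_neg)
}

#' Deviation of traction magnitude (DTM)
#'
#' Mean relative magnitude error at the true force points:
#' mean over positives of (|f_est| - |F|) / |F|. Zero is perfect; negative
#' values mean underestimation, with -1 meaning the estimate is essentially
#' zero; positive values mean overestimation.
#'
#' @inheritParams roc_auc
#' @return scalar DTM.
#' @export
dtm <- function(est, truth) {
  check_same_grid(est, truth)
  tm <- force_magnitudes(truth)
  pos <- tm > 0
  if (!any(pos)) stop("no positive (true force) points", call. = FALSE)
  em <- force_magnitudes(est)
  mean((em[pos] - tm[pos]) / tm[pos])
}

#' Deviation of traction magnitude in the background (DTMB)
#'
#' Mean over negative points of the estimated magnitude divided by the
#' average true magnitude at the positive points: how large false-positive
#' forces are relative to the real ones. 0 means a clean background; values
#' near 1 mean spurious forces as large as the true ones.
#'
#' @inheritParams roc_auc
#' @return scalar DTMB (>= 0).
#' @export
dtmb <- function(est, truth, region = NULL) {
  check_same_grid(est, truth)
  if (is.null(region)) region <- truth$inside_cell
  tm <- force_magnitudes(truth)
  pos <- tm > 0
  if (!any(pos)) stop("no positive points: mean true magnitude undefined",
                      call. = FALSE)
  neg <- region & !pos
  if (!any(neg)) stop("no negative points in the evaluation region",
                      call. = FALSE)
  em <- force_magnitudes(est)
  mean(em[neg]) / mean(tm[pos])
}

#' Evaluate one estimate against the dataset's ground truth
#'
#' @param est a `btfe_fit`, `baseline_fit`, or force-field tibble.
#' @param ds the `tfm_dataset` the estimate was computed on.
#' @return one-row tibble: auc, dtm, dtmb, m_pos, m_neg.
#' @export
evaluate_estimate <- function(est, ds) {
  field <- if (is.data.frame(est)) est else est$forces
  r <- roc_auc(field, ds$true_forces)
  tibble::tibble(auc = r$auc,
                 dtm = dtm(field, ds$true_forces),
                 dtmb = dtmb(field, ds$true_forces),
                 m_pos = r$m_pos, m_neg = r$m_neg)
}

#' Run the synthetic benchmark grid
#'
#' For every cell (a boundary configuration), density, and replicate, a
#' fresh bead scatter and observation noise are drawn while the boundary
#' and true forces stay fixed; every requested algorithm then runs on
#' identical inputs and is scored with AUC, DTM, and DTMB on the interior
#' grid points. Failures of a single estimator are recorded (`error`
#' column), not fatal.
#'
#' @param cells named list of [tfm_config()] objects, one per model cell.
#' @param densities bead densities (per um^2) to run.
#' @param algorithms subset of c("btfe", "ridge", "lasso").
#' @param n_replicates bead patterns per condition (default 10).
#' @param seed master seed; every cell/replicate seed derives from it.
#' @param n_restarts EM restarts for btfe. The Bayesian estimator receives
#'   the generator's mean force magnitude as its prior scale — the typical
#'   traction of the model cell is treated as known biology, like the
#'   boundary itself.
#' @return tidy tibble, one row per algorithm x cell x density x replicate,
#'   with columns cell, density, replicate, algorithm, auc, dtm, dtmb,
#'   n_beads, error.
#' @export
run_benchmark <- function(cells, densities = c(0.4, 1.6),
                          algorithms = c("btfe", "ridge", "lasso"),
                          n_replicates = 10, seed = 1, n_restarts = 5) {
  stopifnot(is.list(cells), length(cells) >= 1)
  if (is.null(names(cells)) || any(names(cells) == ""))
    names(cells) <- paste0("cell", seq_along(cells))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  cell_seeds <- derive_seeds(seed, length(cells))
  rows <- list()
  for (ci in seq_along(cells)) {
    cfg <- cells[[ci]]
    ds0 <- make_dataset(cfg, seed = cell_seeds[ci])
    rep_seeds <- derive_seeds(cell_seeds[ci] %% 1000000L + 7L,
                              n_replicates * length(densities))
    k <- 0
    for (dens in densities) {
      ds0$config$bead_density <- dens
      for (rep in seq_len(n_replicates)) {
        k <- k + 1
        ds <- resample_beads(ds0, bead_seed = rep_seeds[k])
        for (alg in algorithms) {
          res <- tryCatch({
            fit <- switch(alg,
              btfe = btfe(ds$beads, ds$mask, substrate = ds$substrate,
                          grid = ds$grid, prior = ds$prior,
                          prior_scale = cfg$force_magnitude,
                          n_restarts = n_restarts, seed = rep_seeds[k]),
              ridge = tfm_baseline(ds$beads, ds$mask, method = "ridge",
                                   substrate = ds$substrate, grid = ds$grid,
                                   seed = rep_seeds[k]),
              lasso = tfm_baseline(ds$beads, ds$mask, method = "lasso",
                                   substrate = ds$substrate, grid = ds$grid,
                                   seed = rep_seeds[k]))
            ev <- evaluate_estimate(fit, ds)
            dplyr::mutate(ev, error = NA_character_)
          }, error = function(e) {
            tibble::tibble(auc = NA_real_, dtm = NA_real_, dtmb = NA_real_,
                           m_pos = NA_integer_, m_neg = NA_integer_,
                           error = conditionMessage(e))
          })
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(cell = names(cells)[ci], density = dens,
                           replicate = rep, algorithm = alg,
                           n_beads = nrow(ds$beads)),
            res)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tfm_benchmark", class(out))
  out
}

#' Summarize a benchmark table: mean and standard error per condition
#'
#' @param bench tibble from [run_benchmark()].
#' @return tibble with one row per algorithm x cell x density and
#'   mean/SE columns for auc, dtm, dtmb.
#' @export
summarize_benchmark <- function(bench) {
  bench |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$algorithm, .data$cell, .data$density) |>
    dplyr::summarise(
      dplyr::across(c("auc", "dtm", "dtmb"),
                    list(mean = mean,
                         se = ~ stats::sd(.x) / sqrt(length(.x)))),
      n = dplyr::n(), .groups = "drop")
}
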