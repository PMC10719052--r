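#' Standard synthetic benchmark cells
#'
#' The study conditions of the synthetic benchmark: three complex lobed
#' cells (high-amplitude blob boundaries, synthetic stand-ins for irregular
#' motile-cell outlines) and two near-round cells (low-amplitude blobs).
#' Each cell carries 20 noisy inward traction points of mean magnitude 10
#' (boundary-biased placement), and is observed through beads with
#' displacement noise sd 0.1 um.
#'
#' @param field_px raster side (pixels) at 0.2 um/px; 96 px (a 19.2 um
#'   field, cells of roughly 100 um^2, the size of a small motile cell)
#'   keeps a full benchmark run in the minutes range.
#' @return named list with elements `complex` and `round`, each a named
#'   list of [tfm_config()] objects.
#' @export
standard_benchmark_cells <- function(field_px = 96) {
  complex <- lapply(1:3, function(i)
    tfm_config(shape = "blob", blob_amplitude = 0.35, field_px = field_px))
  names(complex) <- paste0("complex", 1:3)
  round_ <- lapply(1:2, function(i)
    tfm_config(shape = "blob", blob_amplitude = 0.08, field_px = field_px))
  names(round_) <- paste0("round", 1:2)
  list(complex = complex, round = round_)
}

#' Run the full standard benchmark
#'
#' Complex cells are run with all three estimators at the low bead density
#' (0.4 beads/um^2) and with the Bayesian estimator alone at the middle
#' density (1.6 beads/um^2); near-round cells are run with the Bayesian
#' estimator at both densities. Each condition uses `n_replicates`
#' independent bead scatters over a fixed force pattern per cell. Cell
#' boundaries, force patterns, and bead scatters all derive from `seed`.
#'
#' @param seed master seed.
#' @param n_replicates bead patterns per condition (default 10).
#' @param field_px raster side passed to [standard_benchmark_cells()].
#' @return tidy tibble as from [run_benchmark()] plus a `boundary_class`
#'   column (`"complex"` or `"round"`).
#' @export
benchmark_suite <- function(seed = 1, n_replicates = 10, field_px = 96) {
  cells <- standard_benchmark_cells(field_px)
  b_complex_low <- run_benchmark(cells$complex, densities = 0.4,
                                 algorithms = c("btfe", "ridge", "lasso"),
                                 n_replicates = n_replicates, seed = seed)
  b_complex_mid <- run_benchmark(cells$complex, densities = 1.6,
                                 algorithms = "btfe",
                                 n_replicates = n_replicates, seed = seed)
  b_round <- run_benchmark(cells$round, densities = c(0.4, 1.6),
                           algorithms = "btfe",
                           n_replicates = n_replicates, seed = seed + 1L)
  dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(b_complex_low, b_complex_mid),
                  boundary_class = "complex"),
    dplyr::mutate(b_round, boundary_class = "round"))
}

#' Headline summary values of a standard benchmark run
#'
#' @param bench table from [benchmark_suite()].
#' @return named list: `lasso_auc_complex_low` (mean lasso AUC, complex
#'   cells, 0.4 beads/um^2), `btfe_auc_round` (mean Bayesian AUC on round
#'   cells over both densities), `baseline_dtm_complex_low` (mean of the
#'   ridge and lasso DTM means at the complex/low condition),
#'   `btfe_dtmb_max` (largest per-condition mean DTMB of the Bayesian
#'   estimator), each with the number of fits it aggregates.
#' @export
benchmark_headline <- function(bench) {
  ok <- dplyr::filter(bench, is.na(.data$error))
  cl <- dplyr::filter(ok, .data$boundary_class == "complex",
                      .data$density == 0.4)
  lasso_auc <- mean(cl$auc[cl$algorithm == "lasso"])
  rl_dtm <- mean(c(mean(cl$dtm[cl$algorithm == "ridge"]),
                   mean(cl$dtm[cl$algorithm == "lasso"])))
  rd <- dplyr::filter(ok, .data$boundary_class == "round",
                      .data$algorithm == "btfe")
  btfe_round_auc <- mean(rd$auc)
  dtmb_cond <- ok |>
    dplyr::filter(.data$algorithm == "btfe") |>
    dplyr::group_by(.data$cell, .data$density) |>
    dplyr::summarise(dtmb = mean(.data$dtmb), n = dplyr::n(),
                     .groups = "drop")
  list(
    lasso_auc_complex_low = list(value = lasso_auc,
                                 n = sum(cl$algorithm == "lasso")),
    btfe_auc_round = list(value = btfe_round_auc, n = nrow(rd)),
    baseline_dtm_complex_low = list(
      value = rl_dtm, n = sum(cl$algorithm %in% c("ridge", "lasso"))),
    btfe_dtmb_max = list(value = max(dtmb_cond$dtmb),
                         n = sum(dtmb_cond$n)))
}

#' Fraction of total estimated force magnitude inside the cell
#'
#' The Bayesian estimator confines force to the cellular region; ridge
#' spreads small forces across the boundary and lasso places sparse spikes
#' wherever beads demand them, so their interior fractions are lower.
#'
#' @param est a fit object or force-field tibble.
#' @param ds the `tfm_dataset` (supplies the interior indicator).
#' @return scalar in `[0, 1]`.
#' @export
interior_fraction <- function(est, ds) {
  field <- if (is.data.frame(est)) est else est$forces
  mag <- sqrt(field$fx^2 + field$fy^2)
  if (sum(mag) == 0) return(NA_real_)
  sum(mag[field$inside_cell]) / sum(mag)
}
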