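# Shared small fixtures, memoised so expensive objects build once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 64 px field (12.8 um) keeps unit tests fast; benchmarks use larger fields.
tiny_config <- function(...) {
  tfm_config(field_px = 64, bead_density = 0.4, ...)
}

tiny_dataset <- function(seed = 1) {
  memo(paste0("tiny_ds_", seed), make_dataset(tiny_config(), seed = seed))
}

# small circular mask + grid for geometry tests
circle_mask <- function(dim = 64, R_px = 20, px = 0.5) {
  memo(sprintf("circle_%d_%d_%g", dim, R_px, px),
       generate_boundary("circle", dim = c(dim, dim), pixel_size = px,
                         size = R_px * px))
}

# random toy linear system (B beads, N grid points) built from a real grid
toy_system <- function(seed = 42, n_beads = 6, dim = 32, rows = 4, cols = 4) {
  withr::with_seed(seed, {
    mask <- generate_boundary("circle", dim = c(dim, dim), pixel_size = 0.5,
                              size = 5)
    grid <- force_grid(mask, rows = rows, cols = cols)
    beads <- tibble::tibble(
      bead_id = seq_len(n_beads),
      x_um = stats::runif(n_beads, 1, dim * 0.5 - 1),
      y_um = stats::runif(n_beads, 1, dim * 0.5 - 1))
    list(mask = mask, grid = grid, beads = beads,
         substrate = elastic_substrate(1, 0.5))
  })
}
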