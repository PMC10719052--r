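#' Read a bead table from CSV
#'
#' Expected columns: `bead_id,x_um,y_um,ux_um,uy_um` (header required).
#' Positions in um, displacements in um.
#'
#' @param path CSV file path.
#' @return bead tibble.
#' @export
read_beads <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("bead_id", "x_um", "y_um", "ux_um", "uy_um")
  missing <- setdiff(need, names(tb))
  if (length(missing) > 0)
    stop("bead CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tb[need]
}

#' Write a bead table to CSV
#' @param beads bead tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beads <- function(beads, path) {
  readr::write_csv(beads, path)
  invisible(path)
}

#' Read a force field from CSV
#'
#' Expected columns `grid_i,grid_j,x_um,y_um,fx,fy,inside_cell`.
#'
#' @param path CSV file path.
#' @return force-field tibble.
#' @export
read_forces <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("grid_i", "grid_j", "x_um", "y_um", "fx", "fy", "inside_cell")
  missing <- setdiff(need, names(tb))
  if (length(missing) > 0)
    stop("force CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tb$inside_cell <- as.logical(tb$inside_cell)
  tb[c(need, setdiff(names(tb), need))]
}

#' Write a force field (or prior field) to CSV
#' @param field force-field tibble (extra columns such as `m`, `dx`, `dy`
#'   are kept).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forces <- function(field, path) {
  readr::write_csv(field, path)
  invisible(path)
}

#' Load a cell mask from a raster image or polygon CSV
#'
#' PNG/TIFF: any nonzero pixel (first channel) is foreground. Polygon CSV
#' (columns `vertex_id,x_um,y_um`) is rasterized at `pixel_size` onto a
#' raster of `dim` pixels.
#'
#' @param path file path (.png, .tif/.tiff, or .csv).
#' @param pixel_size um per pixel.
#' @param dim raster dimensions c(rows, cols); required for polygon input.
#' @param largest_component keep only the largest connected component
#'   instead of erroring on fragmented masks.
#' @return A [cell_mask()].
#' @export
load_mask <- function(path, pixel_size, dim = NULL,
                      largest_component = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tb <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("vertex_id", "x_um", "y_um")
    if (!all(need %in% names(tb)))
      stop("polygon CSV must have columns vertex_id,x_um,y_um", call. = FALSE)
    if (is.null(dim))
      stop("`dim` is required to rasterize a polygon mask", call. = FALSE)
    tb <- tb[order(tb$vertex_id), ]
    return(rasterize_polygon(cbind(tb$x_um, tb$y_um), dim, pixel_size))
  }
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext, call. = FALSE))
  if (length(base::dim(img)) == 3) img <- img[, , 1]
  cell_mask(img > 0, pixel_size, largest_component = largest_component)
}

#' Write a cell mask as a single-channel TIFF
#' @param mask a [cell_mask()].
#' @param path output path (.tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cell_mask"))
  tiff::writeTIFF(mask$raster * 1, path)
  invisible(path)
}

#' Read an estimation run configuration from YAML
#'
#' Recognized top-level keys match the arguments of [tfm_config()],
#' [btfe_hyperparams()] (`alpha`, `beta`, `gamma`, `sigma2_fraction`) and
#' the EM controls (`n_restarts`, `tol`, `max_iter`); unknown keys raise an
#' error so typos fail fast, and every value is validated by the downstream
#' constructors before any computation.
#'
#' @param path YAML file path.
#' @return list with elements `config` ([tfm_config()]), `hyperparams`
#'   ([btfe_hyperparams()]) and `em` (list of EM controls).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg_keys <- names(formals(tfm_config))
  hp_keys <- names(formals(btfe_hyperparams))
  em_keys <- c("n_restarts", "tol", "max_iter")
  unknown <- setdiff(names(raw), c(cfg_keys, hp_keys, em_keys))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- do.call(tfm_config, raw[intersect(names(raw), cfg_keys)])
  hp <- do.call(btfe_hyperparams, raw[intersect(names(raw), hp_keys)])
  em <- utils::modifyList(list(n_restarts = 5, tol = 1e-6, max_iter = 200),
                          raw[intersect(names(raw), em_keys)])
  stopifnot(em$n_restarts >= 1, em$tol > 0, em$max_iter >= 1)
  list(config = cfg, hyperparams = hp, em = em)
}

#' Write a run manifest (config echo, seeds, package version) as JSON
#' @param path output path.
#' @param config configuration list (echoed verbatim).
#' @param seed master seed of the run.
#' @param extra optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  manifest <- c(list(
    package = "bayestfm",
    version = as.character(utils::packageVersion("bayestfm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
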