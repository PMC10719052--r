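#' Binary cell mask on a pixel raster
#'
#' @param raster logical (or 0/1 numeric) matrix, TRUE = cell. Rows are the
#'   image y axis (down), columns the x axis (right).
#' @param pixel_size pixel edge length in um.
#' @param largest_component if TRUE, keep only the largest connected
#'   foreground component; otherwise a multi-component mask is an error.
#' @return An object of class `cell_mask`: list(raster, pixel_size).
#' @export
cell_mask <- function(raster, pixel_size, largest_component = FALSE) {
  stopifnot(is.matrix(raster), is.numeric(pixel_size), length(pixel_size) == 1,
            pixel_size > 0)
  m <- raster != 0
  m[is.na(m)] <- FALSE
  if (!any(m)) stop("cell mask is empty", call. = FALSE)
  if (all(m)) stop("cell mask covers the whole raster; no boundary exists",
                   call. = FALSE)
  lab <- EBImage::bwlabel(m * 1)
  ncomp <- max(lab)
  if (ncomp > 1) {
    if (!largest_component)
      stop(sprintf(paste0("mask has %d connected components; pass ",
                          "largest_component = TRUE to keep the biggest"),
                   ncomp), call. = FALSE)
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    m <- lab == which.max(sizes)
  }
  structure(list(raster = m, pixel_size = pixel_size), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d px @ %g um/px, area %.1f um^2\n",
              nrow(x$raster), ncol(x$raster), x$pixel_size, mask_area(x)))
  invisible(x)
}

#' Cell area in um^2
#' @param mask a [cell_mask()].
#' @return scalar area (foreground pixel count times pixel area).
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  sum(mask$raster) * mask$pixel_size^2
}
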