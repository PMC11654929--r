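#' Lightweight in-memory raster grid
#'
#' `raster_grid` is the package's container for gridded spatial layers: a list
#' of equally-sized matrices ("bands") sharing one geographic (WGS84 lon/lat)
#' georeferencing. Matrices follow image convention: row 1 is the northernmost
#' row of pixels, column 1 the westernmost. Cell values are pixel-center
#' point values; `NA` marks nodata.
#'
#' @param xmin,ymin Coordinates of the lower-left corner of the grid (degrees).
#' @param res Pixel size in degrees (square pixels).
#' @param nrow,ncol Grid dimensions.
#' @param bands Named list of `nrow` x `ncol` numeric matrices.
#' @param inside Optional logical matrix marking pixels inside the analysis
#'   boundary (used by imputation to distinguish holes from exterior).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(xmin, ymin, res, nrow, ncol, bands = list(), inside = NULL) {
  stopifnot(res > 0, nrow >= 1, ncol >= 1)
  bands <- lapply(bands, function(m) {
    m <- as.matrix(m)
    stopifnot(identical(dim(m), c(as.integer(nrow), as.integer(ncol))))
    storage.mode(m) <- "double"
    m
  })
  structure(
    list(xmin = xmin, ymin = ymin, res = res,
         nrow = as.integer(nrow), ncol = as.integer(ncol),
         bands = bands, inside = inside, crs = "EPSG:4326"),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d pixels @ %g deg, origin (%g, %g)\n",
              x$nrow, x$ncol, x$res, x$xmin, x$ymin))
  cat("bands:", if (length(x$bands)) paste(names(x$bands), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

rg_ymax <- function(rg) rg$ymin + rg$nrow * rg$res
rg_xmax <- function(rg) rg$xmin + rg$ncol * rg$res

# Pixel-center coordinates of every cell, row-major from the top-left.
rg_centers <- function(rg) {
  lon <- rg$xmin + (seq_len(rg$ncol) - 0.5) * rg$res
  lat <- rg_ymax(rg) - (seq_len(rg$nrow) - 0.5) * rg$res
  list(lon = lon, lat = lat)
}

#' Tidy view of a raster grid
#'
#' @param rg A [raster_grid()].
#' @return A tibble with one row per pixel: `row`, `col`, `lon`, `lat`, one
#'   column per band, and `inside` if the grid carries a boundary mask.
#' @export
rg_as_tibble <- function(rg) {
  stopifnot(inherits(rg, "raster_grid"))
  ctr <- rg_centers(rg)
  out <- tidyr::expand_grid(row = seq_len(rg$nrow), col = seq_len(rg$ncol))
  out$lon <- ctr$lon[out$col]
  out$lat <- ctr$lat[out$row]
  for (b in names(rg$bands)) out[[b]] <- rg$bands[[b]][cbind(out$row, out$col)]
  if (!is.null(rg$inside)) out$inside <- rg$inside[cbind(out$row, out$col)]
  tibble::as_tibble(out)
}

# Row/col of the cell containing each point; NA outside the footprint.
rg_cell <- function(rg, lon, lat) {
  col <- floor((lon - rg$xmin) / rg$res) + 1
  row <- floor((rg_ymax(rg) - lat) / rg$res) + 1
  # points exactly on the top/right edge belong to the edge cell
  col[lon == rg_xmax(rg)] <- rg$ncol
  row[lat == rg$ymin] <- rg$nrow
  bad <- col < 1 | col > rg$ncol | row < 1 | row > rg$nrow | !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}
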