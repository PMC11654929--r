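# Minimal GeoTIFF I/O: uncompressed little-endian float32, chunky interleave,
# one strip, geographic (EPSG:4326) georeferencing via ModelPixelScale +
# ModelTiepoint, nodata advertised through the GDAL nodata tag. This covers
# exactly the rasters this package produces; it is not a general TIFF library.

GTIFF_NODATA <- -9999

#' Write a raster grid as a GeoTIFF
#'
#' Bands are stored as 32-bit IEEE floats with nodata sentinel -9999 in place
#' of `NA`; georeferencing is geographic WGS84 pixel-is-area. The file round
#' trips losslessly (at float32 precision) through [read_geotiff()].
#'
#' @param rg A [raster_grid()] with at least one band.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(rg, path) {
  stopifnot(inherits(rg, "raster_grid"), length(rg$bands) >= 1)
  nb <- length(rg$bands); w <- rg$ncol; h <- rg$nrow
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))

  # pixel payload: chunky interleave, row-major from the top-left
  arr <- array(NA_real_, c(nb, w, h))
  for (i in seq_len(nb)) arr[i, , ] <- t(rg$bands[[i]])
  px <- as.numeric(arr)
  px[is.na(px)] <- GTIFF_NODATA

  band_names <- paste(names(rg$bands), collapse = "|")
  ascii_nodata <- c(charToRaw(as.character(GTIFF_NODATA)), as.raw(0))
  ascii_desc <- c(charToRaw(band_names), as.raw(0))

  n_tags <- 17L
  ifd_off <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  ext_off <- ifd_off + ifd_size
  pad <- function(n) (n + 1L) %/% 2L * 2L
  off_scale <- pad(ext_off)
  off_tie <- off_scale + 24L
  off_geokeys <- off_tie + 48L
  off_nodata <- off_geokeys + 32L
  off_desc <- pad(off_nodata + length(ascii_nodata))
  off_bps <- pad(off_desc + length(ascii_desc))      # BitsPerSample values if nb > 2
  off_sf <- off_bps + (if (nb > 2L) 2L * nb else 0L) # SampleFormat values if nb > 2
  off_data <- pad(off_sf + (if (nb > 2L) 2L * nb else 0L))

  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  tag <- function(id, type, count, value, inline_short = FALSE) {
    w2(id); w2(type); w4(count)
    if (inline_short) { w2(value); w2(0L) } else w4(value)
  }

  writeChar("II", con, eos = NULL); w2(42L); w4(ifd_off)
  w2(n_tags)
  tag(256, 3, 1, w, inline_short = TRUE)                      # ImageWidth
  tag(257, 3, 1, h, inline_short = TRUE)                      # ImageLength
  if (nb == 1L) tag(258, 3, 1, 32L, inline_short = TRUE)
  else if (nb == 2L) { w2(258L); w2(3L); w4(2L); w2(32L); w2(32L) }
  else tag(258, 3, nb, off_bps)                               # BitsPerSample
  tag(259, 3, 1, 1L, inline_short = TRUE)                     # Compression: none
  tag(262, 3, 1, 1L, inline_short = TRUE)                     # Photometric: BlackIsZero
  if (length(ascii_desc) <= 4L) {                             # ImageDescription: band names
    w2(270L); w2(2L); w4(length(ascii_desc))
    writeBin(c(ascii_desc, raw(4L - length(ascii_desc))), con)
  } else tag(270, 2, length(ascii_desc), off_desc)
  tag(273, 4, 1, off_data)                                    # StripOffsets
  tag(277, 3, 1, nb, inline_short = TRUE)                     # SamplesPerPixel
  tag(278, 4, 1, h)                                           # RowsPerStrip
  tag(279, 4, 1, length(px) * 4L)                             # StripByteCounts
  tag(284, 3, 1, 1L, inline_short = TRUE)                     # PlanarConfiguration: chunky
  if (nb == 1L) tag(339, 3, 1, 3L, inline_short = TRUE)
  else if (nb == 2L) { w2(339L); w2(3L); w4(2L); w2(3L); w2(3L) }
  else tag(339, 3, nb, off_sf)                                # SampleFormat: IEEE float
  tag(33550, 12, 3, off_scale)                                # ModelPixelScale
  tag(33922, 12, 6, off_tie)                                  # ModelTiepoint
  tag(34735, 3, 16, off_geokeys)                              # GeoKeyDirectory
  tag(42112, 2, 1, 0L, inline_short = TRUE)                   # (reserved, empty)
  tag(42113, 2, length(ascii_nodata), off_nodata)             # GDAL nodata
  w4(0L)                                                      # next IFD

  pad_to <- function(target) {
    cur <- seek(con, where = NA)
    if (cur < target) writeBin(raw(target - cur), con)
  }
  pad_to(off_scale)
  writeBin(c(rg$res, rg$res, 0), con, size = 8, endian = "little")
  writeBin(c(0, 0, 0, rg$xmin, rg_ymax(rg), 0), con, size = 8, endian = "little")
  # GeoKeys: version 1.1.0; ModelType = geographic; RasterType = PixelIsArea;
  # GeographicType = 4326
  w2(c(1L, 1L, 0L, 3L,
       1024L, 0L, 1L, 2L,
       1025L, 0L, 1L, 1L,
       2048L, 0L, 1L, 4326L))
  writeBin(ascii_nodata, con)
  pad_to(off_desc)
  writeBin(ascii_desc, con)
  if (nb > 2L) {
    pad_to(off_bps)
    w2(rep(32L, nb)); w2(rep(3L, nb))
  }
  pad_to(off_data)
  writeBin(px, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a GeoTIFF written by [write_geotiff()]
#'
#' @param path File path.
#' @return A [raster_grid()]; sentinel values become `NA`.
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.info(path)$size)
  le <- rawToChar(raw[1:2]) == "II"
  if (!le && rawToChar(raw[1:2]) != "MM") stop("not a TIFF file: ", path, call. = FALSE)
  endian <- if (le) "little" else "big"
  rint <- function(off, size, n = 1) # off is 0-based
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2)
  rdbl <- function(off, n)
    readBin(raw[(off + 1):(off + 8 * n)], "double", n = n, size = 8, endian = endian)

  ifd <- rint(4, 4)
  n_tags <- rint(ifd, 2)
  tags <- list()
  type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `12` = 8)
  for (k in seq_len(n_tags)) {
    e <- ifd + 2 + (k - 1) * 12
    id <- rint(e, 2); type <- rint(e + 2, 2); count <- rint(e + 4, 4)
    ts <- type_size[[as.character(type)]]
    nbytes <- ts * count
    voff <- if (nbytes <= 4) e + 8 else rint(e + 8, 4)
    val <- switch(as.character(type),
      `2` = rawToChar(raw[(voff + 1):(voff + count)][raw[(voff + 1):(voff + count)] != as.raw(0)]),
      `12` = rdbl(voff, count),
      rint(voff, ts, count))
    tags[[as.character(id)]] <- val
  }
  need <- function(id) tags[[as.character(id)]] %||% stop("missing TIFF tag ", id, call. = FALSE)
  w <- need(256); h <- need(257); nb <- tags[["277"]] %||% 1L
  if ((tags[["259"]] %||% 1L) != 1L) stop("only uncompressed TIFFs are supported", call. = FALSE)
  if (any((tags[["339"]] %||% 3L) != 3L)) stop("only float sample format is supported", call. = FALSE)
  offs <- need(273); counts <- need(279)
  vals <- unlist(lapply(seq_along(offs), function(i)
    readBin(raw[(offs[i] + 1):(offs[i] + counts[i])], "double",
            n = counts[i] / 4, size = 4, endian = endian)))
  scale <- need(33550); tie <- need(33922)
  res <- scale[1]
  xmin <- tie[4]; ymax <- tie[5]
  nodata <- suppressWarnings(as.numeric(tags[["42113"]] %||% NA))
  band_names <- if (!is.null(tags[["270"]]) && nzchar(tags[["270"]]))
    strsplit(tags[["270"]], "|", fixed = TRUE)[[1]] else paste0("band", seq_len(nb))

  arr <- array(vals, c(nb, w, h))
  bands <- setNames(lapply(seq_len(nb), function(i) {
    m <- t(arr[i, , , drop = TRUE])
    dim(m) <- c(h, w)
    if (!is.na(nodata)) m[m == nodata] <- NA_real_
    m
  }), band_names[seq_len(nb)])
  raster_grid(xmin = xmin, ymin = ymax - h * res, res = res,
              nrow = h, ncol = w, bands = bands)
}
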