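#' @importFrom rlang %||% .data
#' @importFrom stats plogis qlogis rnorm runif rbinom optim nlminb sd var median quantile setNames complete.cases dist
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a master seed and a stage label, stably across
# sessions (no RNG use; keeps per-stage streams independent).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 104729L)) %% 2147483562L + 1L
}

# Boundary polygons are plain data frames / matrices with lon, lat columns.
as_boundary <- function(boundary) {
  b <- as.data.frame(boundary)
  if (!all(c("lon", "lat") %in% names(b))) {
    if (ncol(b) >= 2) names(b)[1:2] <- c("lon", "lat")
  }
  b <- b[, c("lon", "lat")]
  if (nrow(b) < 3) stop("boundary polygon needs at least 3 vertices", call. = FALSE)
  b
}

# Shoelace area in squared degrees (sign dropped); used only for degeneracy checks.
poly_area_deg2 <- function(boundary) {
  b <- as_boundary(boundary)
  x <- b$lon; y <- b$lat
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

points_in_poly <- function(lon, lat, boundary) {
  b <- as_boundary(boundary)
  mgcv::in.out(as.matrix(b), cbind(lon, lat))
}

# Uniform points inside a polygon by rejection from the bounding box.
runif_in_poly <- function(n, boundary) {
  b <- as_boundary(boundary)
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    lon <- runif(m, min(b$lon), max(b$lon))
    lat <- runif(m, min(b$lat), max(b$lat))
    keep <- points_in_poly(lon, lat, b)
    out <- rbind(out, cbind(lon[keep], lat[keep]))
  }
  tibble::tibble(lon = out[seq_len(n), 1], lat = out[seq_len(n), 2])
}

#' Default rectangular study boundary
#'
#' A simple 10 x 10 degree rectangle used as the default synthetic country.
#'
#' @param lon_min,lat_min Lower-left corner in degrees.
#' @param width,height Extent in degrees.
#' @return A tibble of polygon vertices with columns `lon`, `lat`.
#' @export
default_boundary <- function(lon_min = 10, lat_min = -5, width = 10, height = 10) {
  tibble::tibble(
    lon = c(lon_min, lon_min + width, lon_min + width, lon_min),
    lat = c(lat_min, lat_min, lat_min + height, lat_min + height)
  )
}
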