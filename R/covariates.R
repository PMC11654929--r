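# Model CRS: world Mollweide (equal-area, spherical formulation on the WGS84
# semi-major axis), rescaled to kilometers. All mesh and variogram distances
# live in this plane.

MOLL_R <- 6378137 # meters

#' Transform lon/lat to model coordinates (Mollweide, km)
#'
#' @param lon,lat Coordinates in decimal degrees (WGS84).
#' @return A tibble with columns `x_km`, `y_km`.
#' @export
to_model_crs <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  theta <- phi
  for (i in 1:50) {
    f <- 2 * theta + sin(2 * theta) - pi * sin(phi)
    fp <- 2 + 2 * cos(2 * theta)
    step <- ifelse(fp < 1e-12, 0, f / pmax(fp, 1e-12))
    theta <- theta - step
    if (max(abs(step)) < 1e-14) break
  }
  tibble::tibble(
    x_km = MOLL_R * (2 * sqrt(2) / pi) * lam * cos(theta) / 1000,
    y_km = MOLL_R * sqrt(2) * sin(theta) / 1000
  )
}

#' Inverse of [to_model_crs()]
#'
#' @param x_km,y_km Model-plane coordinates in kilometers.
#' @return A tibble with columns `lon`, `lat` in degrees.
#' @export
from_model_crs <- function(x_km, y_km) {
  theta <- asin(pmin(pmax(y_km * 1000 / (MOLL_R * sqrt(2)), -1), 1))
  phi <- asin(pmin(pmax((2 * theta + sin(2 * theta)) / pi, -1), 1))
  lam <- ifelse(abs(cos(theta)) < 1e-12, 0,
                pi * x_km * 1000 / (2 * MOLL_R * sqrt(2) * cos(theta)))
  tibble::tibble(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Log-month time covariate
#'
#' Interview time expressed as continuous months since 2005-01-01 (one month
#' = 30.4375 days) and log transformed with a +1 offset so the origin month
#' is defined.
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts), not before
#'   2005-01-01.
#' @return Numeric vector, `log(months + 1)`.
#' @export
time_covariate <- function(date) {
  d <- as.Date(date)
  if (any(is.na(d))) stop("unparseable interview date", call. = FALSE)
  days <- as.numeric(d - as.Date("2005-01-01"))
  if (any(days < 0)) stop("interview dates before 2005-01-01 are not supported", call. = FALSE)
  log(days / 30.4375 + 1)
}

#' Extract raster values at point locations
#'
#' Nearest-cell (the containing cell's) value per band per point; points
#' outside the raster footprint yield `NA` and are flagged.
#'
#' @param stack A [raster_grid()] with one or more bands.
#' @param points A data frame with `lon`, `lat` columns.
#' @return `points` with one extra column per band plus a logical
#'   `outside_footprint` column.
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(inherits(stack, "raster_grid"))
  if (length(stack$bands) == 0) stop("covariate stack has no bands", call. = FALSE)
  pts <- tibble::as_tibble(points)
  cell <- rg_cell(stack, pts$lon, pts$lat)
  out <- pts
  for (b in names(stack$bands)) {
    v <- rep(NA_real_, nrow(pts))
    ok <- !is.na(cell$row)
    v[ok] <- stack$bands[[b]][cbind(cell$row[ok], cell$col[ok])]
    out[[b]] <- v
  }
  out$outside_footprint <- is.na(cell$row)
  if (any(out$outside_footprint))
    warning(sum(out$outside_footprint), " point(s) outside the raster footprint", call. = FALSE)
  out
}

#' Build a design matrix with stored encodings
#'
#' Dummy-codes factors against explicit reference levels and (by default)
#' standardizes continuous covariates, recording means/sds and factor levels
#' so the identical encoding can be replayed on prediction-time data.
#'
#' @param data A data frame of covariates (complete cases only).
#' @param continuous Character vector of continuous covariate columns.
#' @param factors Named list: factor column -> reference level.
#' @param standardize Standardize continuous columns to mean 0, sd 1?
#' @return A `design_spec` list with elements `X` (matrix incl. intercept),
#'   `continuous`, `factors`, `levels`, `center`, `scale`, `standardize`.
#' @export
build_design <- function(data, continuous = character(), factors = list(),
                         standardize = TRUE) {
  data <- as.data.frame(data)
  used <- c(continuous, names(factors))
  if (length(used) && any(!complete.cases(data[used])))
    stop("design covariates contain missing values; screen rows first", call. = FALSE)
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  center <- scale_ <- setNames(numeric(length(continuous)), continuous)
  for (v in continuous) {
    x <- as.numeric(data[[v]])
    mu <- if (standardize) mean(x) else 0
    s <- if (standardize) sd(x) else 1
    if (standardize && (!is.finite(s) || s == 0))
      stop("continuous covariate '", v, "' is constant; cannot standardize", call. = FALSE)
    center[v] <- mu; scale_[v] <- s
    X <- cbind(X, matrix((x - mu) / s, ncol = 1, dimnames = list(NULL, v)))
  }
  levels_ <- list()
  for (v in names(factors)) {
    f <- as.character(data[[v]])
    ref <- as.character(factors[[v]])
    levs <- union(ref, sort(unique(f)))
    levels_[[v]] <- levs
    for (l in setdiff(levs, ref)) {
      X <- cbind(X, matrix(as.numeric(f == l), ncol = 1,
                           dimnames = list(NULL, paste0(v, ":", l))))
    }
  }
  structure(list(X = X, continuous = continuous, factors = factors,
                 levels = levels_, center = center, scale = scale_,
                 standardize = standardize),
            class = "design_spec")
}

#' Apply a stored design encoding to new data
#'
#' @param spec A `design_spec` from [build_design()].
#' @param data New covariate rows.
#' @return The design matrix for `data` under the training-time encoding.
#' @export
apply_design <- function(spec, data) {
  stopifnot(inherits(spec, "design_spec"))
  data <- as.data.frame(data)
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in spec$continuous) {
    x <- as.numeric(data[[v]])
    X <- cbind(X, matrix((x - spec$center[v]) / spec$scale[v], ncol = 1,
                         dimnames = list(NULL, v)))
  }
  for (v in names(spec$factors)) {
    f <- as.character(data[[v]])
    levs <- spec$levels[[v]]
    unseen <- setdiff(unique(f), levs)
    if (length(unseen))
      stop("unseen level(s) in '", v, "': ", paste(unseen, collapse = ", "), call. = FALSE)
    ref <- as.character(spec$factors[[v]])
    for (l in setdiff(levs, ref)) {
      X <- cbind(X, matrix(as.numeric(f == l), ncol = 1,
                           dimnames = list(NULL, paste0(v, ":", l))))
    }
  }
  stopifnot(identical(colnames(X), colnames(spec$X)))
  X
}
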