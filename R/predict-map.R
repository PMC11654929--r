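#' Prediction grid over a boundary
#'
#' Pixel centers at the requested resolution covering the boundary's
#' bounding box, with cells outside the polygon masked as nodata.
#'
#' @param boundary Polygon in lon/lat degrees.
#' @param resolution Pixel size in degrees (default 0.05).
#' @return A [raster_grid()] with an `inside` mask and no bands yet, plus
#'   attribute access via [rg_as_tibble()].
#' @export
prediction_grid <- function(boundary, resolution = 0.05) {
  stopifnot(resolution > 0)
  b <- as_boundary(boundary)
  if (poly_area_deg2(b) <= 0) stop("empty boundary", call. = FALSE)
  ncol_ <- max(1L, round((max(b$lon) - min(b$lon)) / resolution))
  nrow_ <- max(1L, round((max(b$lat) - min(b$lat)) / resolution))
  rg <- raster_grid(xmin = min(b$lon), ymin = min(b$lat), res = resolution,
                    nrow = nrow_, ncol = ncol_)
  ctr <- rg_centers(rg)
  lon <- rep(ctr$lon, each = rg$nrow)
  lat <- rep(ctr$lat, times = rg$ncol)
  inside <- matrix(points_in_poly(lon, lat, b), rg$nrow, rg$ncol)
  rg$inside <- inside
  rg
}

#' Predict the prevalence surface
#'
#' Simulates draws of `(w, beta)` from the Gaussian (Laplace) posterior,
#' projects them to pixel centers, and summarizes `logit^-1(eta)` per pixel
#' into a prevalence band (posterior mean) and a standard-error band
#' (posterior sd). The time covariate is fixed at `time_value` for every
#' pixel (by default the log-months value for 2023-01-01).
#'
#' @param fit A `dwell_fit` carrying a `design_spec`.
#' @param grid A [raster_grid()] from [prediction_grid()].
#' @param grid_covariates Tibble of covariates for the unmasked pixels, in
#'   the row order of `rg_as_tibble(grid)` restricted to `inside` pixels;
#'   must contain every design covariate except the time column.
#' @param time_value Value for the `log_time` column (if the design uses
#'   one); default `time_covariate(as.Date("2023-01-01"))`.
#' @param n_draws Number of posterior draws (default 200).
#' @param seed Seed for the draws.
#' @return The grid with bands `prevalence` and `se` added.
#' @export
predict_surface <- function(fit, grid, grid_covariates,
                            time_value = time_covariate(as.Date("2023-01-01")),
                            n_draws = 200, seed = 1L) {
  stopifnot(inherits(fit, "dwell_fit"), inherits(grid, "raster_grid"))
  if (is.null(fit$design_spec)) stop("fit carries no design_spec", call. = FALSE)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  px <- rg_as_tibble(grid)
  inside <- px$inside %||% rep(TRUE, nrow(px))
  pin <- px[inside, ]
  cov <- tibble::as_tibble(grid_covariates)
  stopifnot(nrow(cov) == nrow(pin))
  if ("log_time" %in% c(fit$design_spec$continuous)) cov$log_time <- time_value
  Xg <- apply_design(fit$design_spec, cov)
  xy <- to_model_crs(pin$lon, pin$lat)
  Ag <- projector(fit$mesh, cbind(xy$x_km, xy$y_km))

  draws <- posterior_draws(fit, n_draws, seed)
  eta <- as.matrix(Ag %*% draws$w + Xg %*% draws$beta)
  pp <- plogis(eta)
  prev_in <- rowMeans(pp)
  se_in <- apply(pp, 1, sd)
  if (n_draws == 0) { # plug-in limit
    eta_hat <- drop(as.matrix(Ag %*% fit$field_mean + Xg %*% unname(fit$beta_mean)))
    prev_in <- plogis(eta_hat); se_in <- rep(0, length(prev_in))
  }
  prev <- se <- matrix(NA_real_, grid$nrow, grid$ncol)
  prev[cbind(pin$row, pin$col)] <- prev_in
  se[cbind(pin$row, pin$col)] <- se_in
  grid$bands$prevalence <- prev
  grid$bands$se <- se
  grid
}

# Draws from the Gaussian posterior N(u_hat, H^-1) using the sparse
# Cholesky factorization of the joint precision H (permutation-aware).
posterior_draws <- function(fit, n_draws, seed = 1L) {
  n_vert <- fit$n_vertices
  p <- length(fit$beta_mean)
  if (n_draws == 0)
    return(list(w = matrix(fit$field_mean, ncol = 1),
                beta = matrix(unname(fit$beta_mean), ncol = 1)))
  ch <- Matrix::Cholesky(fit$joint_precision, LDL = FALSE, perm = TRUE)
  z <- with_seed(seed, matrix(rnorm((n_vert + p) * n_draws), n_vert + p, n_draws))
  # H = P' L L' P  =>  u = u_hat + P' L^-T z  has covariance H^-1
  v <- Matrix::solve(ch, z, system = "Lt")
  u <- as.matrix(Matrix::solve(ch, v, system = "Pt")) +
    c(fit$field_mean, unname(fit$beta_mean))
  list(w = u[seq_len(n_vert), , drop = FALSE],
       beta = u[n_vert + seq_len(p), , drop = FALSE])
}

#' Fill missing pixels by k-nearest-neighbour imputation
#'
#' Each nodata pixel inside the boundary mask receives the mean of its `k`
#' nearest valid pixels by great-circle distance between pixel centers; the
#' same neighbour sets are applied to every band so masks stay consistent.
#' Pixels outside the boundary remain nodata. Imputation is idempotent.
#'
#' @param rg A [raster_grid()] with at least one band (and optionally an
#'   `inside` mask; without one, every pixel counts as inside).
#' @param k Number of neighbours (default 5).
#' @return The grid with holes filled.
#' @export
impute_missing_pixels <- function(rg, k = 5) {
  stopifnot(inherits(rg, "raster_grid"), length(rg$bands) >= 1, k >= 1)
  ref <- rg$bands[[1]]
  inside <- rg$inside %||% matrix(TRUE, rg$nrow, rg$ncol)
  valid <- which(!is.na(ref) & inside, arr.ind = TRUE)
  holes <- which(is.na(ref) & inside, arr.ind = TRUE)
  if (nrow(valid) == 0) stop("no valid pixels to impute from", call. = FALSE)
  if (nrow(valid) < k) stop("fewer than k valid pixels", call. = FALSE)
  if (nrow(holes) == 0) return(rg)
  ctr <- rg_centers(rg)
  vxy <- cbind(ctr$lon[valid[, 2]], ctr$lat[valid[, 1]])
  hxy <- cbind(ctr$lon[holes[, 2]], ctr$lat[holes[, 1]])
  for (h in seq_len(nrow(holes))) {
    d <- geosphere::distHaversine(hxy[h, ], vxy)
    nb <- order(d)[seq_len(k)]
    for (b in names(rg$bands)) {
      vals <- rg$bands[[b]][valid[nb, , drop = FALSE]]
      rg$bands[[b]][holes[h, 1], holes[h, 2]] <- mean(vals)
    }
  }
  rg
}

#' Plot a raster band
#'
#' @param rg A [raster_grid()].
#' @param band Band name (default the first).
#' @return A ggplot raster map.
#' @export
plot_raster <- function(rg, band = names(rg$bands)[1]) {
  df <- rg_as_tibble(rg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data[[band]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = band)
}

#' @exportS3Method ggplot2::autoplot
autoplot.raster_grid <- function(object, band = names(object$bands)[1], ...) {
  plot_raster(object, band)
}
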