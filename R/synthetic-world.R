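#' Configuration for the synthetic survey world
#'
#' Bundles every knob of the simulated country: the domain polygon, raster
#' resolution, settlement and cluster counts, household draw per cluster,
#' the generative fixed effects (log-odds), the Matern hyperparameters of
#' the latent field, and the fraction of clusters whose public coordinates
#' are withheld. Defaults describe the study conditions the pipeline is
#' tested under: a ~10 x 10 degree country, 500 clusters of 25-30
#' households, interview dates spanning 2005-2022.
#'
#' @param boundary Polygon (lon/lat degrees), default [default_boundary()].
#' @param raster_res Raster resolution in degrees/pixel.
#' @param n_settlements Number of gazetteer settlements.
#' @param n_clusters Number of survey clusters.
#' @param households_per_cluster Integer interval `c(lo, hi)`.
#' @param n_continuous Number of continuous covariate fields.
#' @param smooth_scale_deg Gaussian smoothing scale of the covariate fields
#'   (degrees); 0 gives i.i.d. pixels.
#' @param use_land_class,use_region,use_time Include the categorical land
#'   class raster, the sub-national region factor, and the log-time
#'   covariate in the generative linear predictor?
#' @param beta Named vector of generative coefficients; names must match the
#'   design columns implied by the toggles (see [simulate_survey()]). `NULL`
#'   picks moderate defaults.
#' @param spatial_range Practical range of the latent Matern field (km).
#' @param spatial_sd Marginal SD of the latent field (log-odds); 0 disables.
#' @param frac_missing_coords Fraction of clusters with coordinates withheld.
#' @param date_range Interview date interval (inclusive).
#' @param seed Master seed of the world.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(boundary = default_boundary(),
                       raster_res = 0.1,
                       n_settlements = 400,
                       n_clusters = 500,
                       households_per_cluster = c(25, 30),
                       n_continuous = 2,
                       smooth_scale_deg = 1,
                       use_land_class = TRUE,
                       use_region = TRUE,
                       use_time = TRUE,
                       beta = NULL,
                       spatial_range = 200,
                       spatial_sd = 1,
                       frac_missing_coords = 0.3,
                       date_range = c("2005-01-01", "2022-12-31"),
                       seed = 1L) {
  stopifnot(raster_res > 0, spatial_range > 0, spatial_sd >= 0,
            frac_missing_coords >= 0, frac_missing_coords <= 1,
            length(households_per_cluster) == 2,
            households_per_cluster[1] >= 1,
            households_per_cluster[2] >= households_per_cluster[1],
            n_settlements >= 1, n_clusters >= 1, n_continuous >= 0)
  boundary <- as_boundary(boundary)
  if (poly_area_deg2(boundary) <= 0) stop("degenerate boundary (zero area)", call. = FALSE)
  cfg <- list(boundary = boundary, raster_res = raster_res,
              n_settlements = as.integer(n_settlements),
              n_clusters = as.integer(n_clusters),
              households_per_cluster = as.integer(households_per_cluster),
              n_continuous = as.integer(n_continuous),
              smooth_scale_deg = smooth_scale_deg,
              use_land_class = use_land_class, use_region = use_region,
              use_time = use_time,
              spatial_range = spatial_range, spatial_sd = spatial_sd,
              frac_missing_coords = frac_missing_coords,
              date_range = as.Date(date_range), seed = as.integer(seed))
  cfg$beta <- beta %||% default_beta(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' High-information simulation profile
#'
#' A [sim_config()] variant describing a strong-signal regime: large
#' covariate effects relative to the latent field, and no withheld
#' coordinates, so the outcome is highly predictable from the model inputs.
#' Used to demonstrate the discriminative ceiling of the pipeline (weak or
#' moderate signal regimes — the default config — bound attainable ROC-AUC
#' well below 1 because a single Bernoulli household per cluster is
#' observed).
#'
#' @param seed Master seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
strong_signal_config <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    spatial_sd = 1, spatial_range = 300, frac_missing_coords = 0,
    beta = c(`(Intercept)` = -0.3, cont_1 = 2.5, cont_2 = -1.5, log_time = 0.3,
             `land_class:class2` = 1.5, `land_class:class3` = -1.0,
             `region:R2` = 0.8, `region:R3` = -0.6, `region:R4` = 0.5),
    ...
  )
}

design_columns <- function(cfg) {
  cols <- "(Intercept)"
  if (cfg$n_continuous > 0) cols <- c(cols, paste0("cont_", seq_len(cfg$n_continuous)))
  if (cfg$use_time) cols <- c(cols, "log_time")
  if (cfg$use_land_class) cols <- c(cols, "land_class:class2", "land_class:class3")
  if (cfg$use_region) cols <- c(cols, "region:R2", "region:R3", "region:R4")
  cols
}

default_beta <- function(cfg) {
  full <- c(`(Intercept)` = -0.5, cont_1 = 0.8, cont_2 = -0.5, cont_3 = 0.3,
            cont_4 = -0.3, log_time = 0.15,
            `land_class:class2` = 0.6, `land_class:class3` = -0.4,
            `region:R2` = 0.3, `region:R3` = -0.2, `region:R4` = 0.2)
  cols <- design_columns(cfg)
  miss <- setdiff(cols, names(full))
  if (length(miss)) stop("no default coefficient for ", paste(miss, collapse = ", "))
  full[cols]
}

# 2 x 2 partition of the domain bounding box into sub-national regions.
region_of <- function(lon, lat, boundary) {
  b <- as_boundary(boundary)
  mx <- mean(range(b$lon)); my <- mean(range(b$lat))
  paste0("R", 1L + (lon >= mx) + 2L * (lat >= my))
}

# Separable Gaussian blur of a matrix; scale in pixels (0 = identity).
gauss_blur <- function(z, scale_px) {
  if (scale_px <= 1e-8) return(z)
  k <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
    exp(-d / (2 * scale_px^2))
  }
  k(nrow(z)) %*% z %*% k(ncol(z))
}

#' Simulate the covariate landscape
#'
#' Smooth unit-variance Gaussian random surfaces for each continuous
#' covariate plus one categorical land-class raster (3 spatially coherent
#' classes cut from a further smooth field), all sharing one grid covering
#' the boundary's bounding box. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A [raster_grid()] with bands `cont_1..k` and `land_class`
#'   (numeric codes 1-3).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$boundary
  res <- config$raster_res
  ncol_ <- max(1L, ceiling((max(b$lon) - min(b$lon)) / res))
  nrow_ <- max(1L, ceiling((max(b$lat) - min(b$lat)) / res))
  scale_px <- config$smooth_scale_deg / res
  with_seed(derive_seed(config$seed, "landscape"), {
    bands <- list()
    for (i in seq_len(config$n_continuous)) {
      z <- gauss_blur(matrix(rnorm(nrow_ * ncol_), nrow_, ncol_), scale_px)
      bands[[paste0("cont_", i)]] <- (z - mean(z)) / sd(z)
    }
    z <- gauss_blur(matrix(rnorm(nrow_ * ncol_), nrow_, ncol_), scale_px)
    q <- quantile(z, c(1 / 3, 2 / 3))
    bands$land_class <- matrix(1 + (z > q[1]) + (z > q[2]), nrow_, ncol_)
    raster_grid(xmin = min(b$lon), ymin = min(b$lat), res = res,
                nrow = nrow_, ncol = ncol_, bands = bands)
  })
}

#' Simulate a settlement gazetteer
#'
#' Settlements placed uniformly inside the boundary with place types drawn
#' from a fixed mix (cities rare, villages common), heavy-tailed
#' (log-normal) population densities whose scale increases with settlement
#' size, urbanicity from [reclassify_place()], and a region from the 2 x 2
#' domain partition. Each region is guaranteed at least one urban and one
#' rural settlement so every survey stratum is matchable.
#'
#' @param boundary Polygon in degrees.
#' @param n_settlements Number of settlements.
#' @param seed Integer seed.
#' @return A settlement tibble.
#' @export
simulate_settlements <- function(boundary, n_settlements, seed = 1L) {
  if (n_settlements < 1) stop("n_settlements must be >= 1", call. = FALSE)
  boundary <- as_boundary(boundary)
  types <- c("city", "town", "village", "hamlet", "isolated dwelling")
  probs <- c(0.05, 0.15, 0.40, 0.30, 0.10)
  meanlog <- c(city = 8, town = 6.5, village = 5, hamlet = 4, `isolated dwelling` = 3)
  with_seed(derive_seed(seed, "settlements"), {
    xy <- runif_in_poly(n_settlements, boundary)
    tp <- sample(types, n_settlements, replace = TRUE, prob = probs)
    region <- region_of(xy$lon, xy$lat, boundary)
    # guarantee stratum coverage: first two settlements of each region become
    # one town and one village
    for (r in unique(region)) {
      idx <- which(region == r)
      if (length(idx) >= 1) tp[idx[1]] <- "town"
      if (length(idx) >= 2) tp[idx[2]] <- "village"
    }
    tibble::tibble(
      settlement_id = seq_len(n_settlements),
      lon = xy$lon, lat = xy$lat,
      place_type = tp,
      urbanicity = reclassify_place(tp),
      region = region,
      population_density = stats::rlnorm(n_settlements, meanlog[tp], 1)
    )
  })
}

#' Simulate a two-stage cluster household survey
#'
#' Clusters are placed at settlements sampled with probability proportional
#' to population density (with a small ~1 km positional jitter, as census
#' enumeration areas sit near but not on the settlement point). A latent
#' Matern Gaussian field is drawn exactly from its dense covariance at the
#' cluster locations; each household's improved/unimproved indicator for
#' each dwelling component is Bernoulli with probability
#' `plogis(x'beta + w(s))`, and is then expressed as a concrete material
#' label of the matching schema class (rudimentary and natural split 50/50
#' within unimproved). Public coordinates are displaced
#' ([displace_coordinates()]) and a configured fraction of clusters has
#' them withheld.
#'
#' @param settlements Gazetteer from [simulate_settlements()].
#' @param covariates Landscape from [simulate_landscape()] (may be `NULL`
#'   when the config requests no raster covariates).
#' @param config A [sim_config()].
#' @return A list of class `dwell_survey`: `households` (one row per
#'   household), `clusters` (cluster-level covariates and public
#'   coordinates), and `truth` (generative beta, range, sd, field values
#'   and true coordinates).
#' @export
simulate_survey <- function(settlements, covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  st <- tibble::as_tibble(settlements)
  if (nrow(st) == 0) stop("empty settlement table", call. = FALSE)
  schema <- material_schema()
  with_seed(derive_seed(config$seed, "survey"), {
    n <- config$n_clusters
    pick <- sample.int(nrow(st), n, replace = TRUE, prob = st$population_density)
    mpd <- meters_per_degree(st$lat[pick])
    b <- config$boundary
    lon <- st$lon[pick] + runif(n, -1000, 1000) / mpd$lon
    lat <- st$lat[pick] + runif(n, -1000, 1000) / mpd$lat
    lon <- pmin(pmax(lon, min(b$lon) + 1e-6), max(b$lon) - 1e-6)
    lat <- pmin(pmax(lat, min(b$lat) + 1e-6), max(b$lat) - 1e-6)
    clusters <- tibble::tibble(
      cluster_id = seq_len(n),
      settlement_id = st$settlement_id[pick],
      region = st$region[pick],
      urbanicity = st$urbanicity[pick],
      lon_true = lon, lat_true = lat,
      interview_date = config$date_range[1] +
        floor(runif(n) * (as.numeric(diff(config$date_range)) + 1))
    )
    # covariates at the true locations
    if (config$n_continuous > 0 || config$use_land_class) {
      if (is.null(covariates)) stop("config requests raster covariates but none given", call. = FALSE)
      ex <- extract_at_points(covariates, clusters[, c("lon_true", "lat_true")] |>
                                dplyr::rename(lon = "lon_true", lat = "lat_true"))
      if (any(ex$outside_footprint))
        stop("covariate stack does not cover all cluster locations", call. = FALSE)
      for (i in seq_len(config$n_continuous))
        clusters[[paste0("cont_", i)]] <- ex[[paste0("cont_", i)]]
      if (config$use_land_class)
        clusters$land_class <- paste0("class", ex$land_class)
    }
    if (config$use_time) clusters$log_time <- time_covariate(clusters$interview_date)

    spec <- build_design(
      clusters,
      continuous = c(if (config$n_continuous > 0) paste0("cont_", seq_len(config$n_continuous)),
                     if (config$use_time) "log_time"),
      factors = c(if (config$use_land_class) list(land_class = "class1"),
                  if (config$use_region) list(region = "R1")),
      standardize = FALSE
    )
    beta <- config$beta
    if (!identical(sort(names(beta)), sort(colnames(spec$X))))
      stop("beta names must match design columns: ",
           paste(colnames(spec$X), collapse = ", "), call. = FALSE)
    eta_fixed <- drop(spec$X %*% beta[colnames(spec$X)])

    w <- numeric(n)
    if (config$spatial_sd > 0) {
      xy <- to_model_crs(clusters$lon_true, clusters$lat_true)
      C <- matern_covariance(cbind(xy$x_km, xy$y_km),
                             matern_params(config$spatial_range, config$spatial_sd))
      L <- chol(C + diag(1e-8 * config$spatial_sd^2, n))
      w <- drop(crossprod(L, rnorm(n)))
    }
    p <- plogis(eta_fixed + w)
    clusters$p_true <- p

    lo <- config$households_per_cluster[1]; hi <- config$households_per_cluster[2]
    n_hh <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    idx <- rep(seq_len(n), n_hh)
    hh <- tibble::tibble(
      household_id = seq_along(idx),
      cluster_id = clusters$cluster_id[idx],
      region = clusters$region[idx],
      urbanicity = clusters$urbanicity[idx],
      interview_date = clusters$interview_date[idx]
    )
    label_pool <- function(comp, cat) {
      sch <- schema[schema$component == comp & schema$category == cat, ]
      sch$label
    }
    for (comp in c("floor", "wall", "roof")) {
      improved <- rbinom(nrow(hh), 1, p[idx]) == 1
      cat <- ifelse(improved, "finished",
                    ifelse(runif(nrow(hh)) < 0.5, "rudimentary", "natural"))
      lab <- character(nrow(hh))
      for (cc in c("natural", "rudimentary", "finished")) {
        pool <- label_pool(comp, cc)
        k <- which(cat == cc)
        lab[k] <- pool[sample.int(length(pool), length(k), replace = TRUE)]
      }
      hh[[paste0(comp, "_material")]] <- lab
    }

    # public coordinates: displaced, a fraction withheld
    disp <- displace_coordinates(clusters$lon_true, clusters$lat_true,
                                 clusters$urbanicity,
                                 seed = derive_seed(config$seed, "displace"),
                                 boundary = config$boundary)
    clusters$lon <- disp$lon; clusters$lat <- disp$lat
    withheld <- sample.int(n, round(config$frac_missing_coords * n))
    clusters$lon[withheld] <- NA_real_; clusters$lat[withheld] <- NA_real_
    hh$lon <- clusters$lon[idx]; hh$lat <- clusters$lat[idx]

    truth <- list(beta = beta, spatial_range = config$spatial_range,
                  spatial_sd = config$spatial_sd, field_values = w,
                  true_cluster_coords = clusters[, c("cluster_id", "lon_true", "lat_true")],
                  design_spec = spec)
    structure(list(households = hh, clusters = clusters, truth = truth),
              class = "dwell_survey")
  })
}
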