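#' Reclassify gazetteer place types to urban/rural
#'
#' Cities and towns are urban; villages, hamlets and isolated dwellings are
#' rural.
#'
#' @param place_type Character vector of place types.
#' @return Character vector `"urban"`/`"rural"`.
#' @export
reclassify_place <- function(place_type) {
  map <- c(city = "urban", town = "urban",
           village = "rural", hamlet = "rural", `isolated dwelling` = "rural")
  key <- normalize_label(place_type)
  bad <- !key %in% names(map)
  if (any(bad))
    stop("unknown place type(s): ", paste(unique(place_type[bad]), collapse = ", "),
         "; allowed: ", paste(names(map), collapse = ", "), call. = FALSE)
  unname(map[key])
}

#' Assign locations to survey clusters
#'
#' Clusters with published (displaced) centroid coordinates keep them
#' (provenance `"centroid"`). Clusters without coordinates are assigned a
#' settlement drawn from the same survey stratum (region x urbanicity) with
#' probability proportional to settlement population density (provenance
#' `"assigned"`); settlements may serve several clusters. If every density
#' in a stratum is equal (including all zero) the draw is uniform. When a
#' stratum has no settlement of matching urbanicity, the default is an
#' error; `fallback_region_only = TRUE` relaxes the match to region alone
#' with a warning.
#'
#' @param clusters Data frame with columns `cluster_id`, `region`,
#'   `urbanicity`, and optional `lon`, `lat` (NA where withheld).
#' @param settlements Settlement gazetteer with `settlement_id`, `lon`,
#'   `lat`, `region`, `urbanicity`, `population_density`.
#' @param seed Integer seed.
#' @param fallback_region_only Relax the urbanicity match when a stratum is
#'   empty?
#' @return A tibble `cluster_id`, `lon`, `lat`, `provenance`,
#'   `settlement_id` (NA for centroid rows).
#' @export
assign_cluster_locations <- function(clusters, settlements, seed = 1L,
                                     fallback_region_only = FALSE) {
  cl <- tibble::as_tibble(clusters)
  st <- tibble::as_tibble(settlements)
  stopifnot(all(c("cluster_id", "region", "urbanicity") %in% names(cl)),
            all(c("settlement_id", "lon", "lat", "region", "urbanicity",
                  "population_density") %in% names(st)))
  if (any(is.na(cl$region) | is.na(cl$urbanicity)))
    stop("cluster stratum (region, urbanicity) must be non-missing", call. = FALSE)
  if (any(st$population_density < 0)) stop("negative population density", call. = FALSE)
  has_xy <- if (all(c("lon", "lat") %in% names(cl))) !is.na(cl$lon) & !is.na(cl$lat)
            else rep(FALSE, nrow(cl))
  out <- tibble::tibble(cluster_id = cl$cluster_id,
                        lon = if ("lon" %in% names(cl)) cl$lon else NA_real_,
                        lat = if ("lat" %in% names(cl)) cl$lat else NA_real_,
                        provenance = ifelse(has_xy, "centroid", "assigned"),
                        settlement_id = NA)
  todo <- which(!has_xy)
  if (length(todo)) {
    draws <- with_seed(seed, {
      vapply(todo, function(i) {
        cand <- which(st$region == cl$region[i] & st$urbanicity == cl$urbanicity[i])
        if (!length(cand)) {
          if (!fallback_region_only)
            stop("no settlement in stratum (", cl$region[i], ", ", cl$urbanicity[i],
                 ") for cluster ", cl$cluster_id[i],
                 "; set fallback_region_only = TRUE to relax", call. = FALSE)
          warning("stratum (", cl$region[i], ", ", cl$urbanicity[i],
                  ") empty; falling back to region-only match", call. = FALSE)
          cand <- which(st$region == cl$region[i])
          if (!length(cand)) stop("no settlement in region ", cl$region[i], call. = FALSE)
        }
        w <- st$population_density[cand]
        if (all(w == w[1])) w <- rep(1, length(w)) # uniform limit of the proportional rule
        cand[sample.int(length(cand), 1, prob = w)]
      }, integer(1))
    })
    out$lon[todo] <- st$lon[draws]
    out$lat[todo] <- st$lat[draws]
    out$settlement_id[todo] <- st$settlement_id[draws]
  }
  out
}

# Meters per degree of latitude/longitude on the WGS84 ellipsoid at latitude
# phi (meridional and normal radii of curvature).
meters_per_degree <- function(lat) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f)
  phi <- lat * pi / 180
  s2 <- sin(phi)^2
  M <- a * (1 - e2) / (1 - e2 * s2)^1.5
  N <- a / sqrt(1 - e2 * s2)
  list(lat = M * pi / 180, lon = N * cos(phi) * pi / 180)
}

#' Displace coordinates for confidentiality
#'
#' Emulates the random displacement applied to published cluster centroids:
#' a uniform random bearing and a uniform random distance up to 2 km for
#' urban clusters and 5 km for rural clusters, with a random 1% of rural
#' clusters displaced up to 10 km. Displaced points falling outside the
#' boundary polygon (when given) are redrawn. Distances are realised via
#' local ellipsoidal (WGS84) meters-per-degree offsets.
#'
#' @param lon,lat Coordinates in degrees.
#' @param urbanicity `"urban"` or `"rural"` per point.
#' @param seed Integer seed.
#' @param boundary Optional polygon the displaced point must stay inside.
#' @param max_km Named displacement caps, default
#'   `c(urban = 2, rural = 5, rural_far = 10)`; `far_fraction` of rural
#'   points use the `rural_far` cap.
#' @param far_fraction Fraction of rural points displaced up to
#'   `max_km["rural_far"]`.
#' @return A tibble `lon`, `lat`, `displacement_km`.
#' @export
displace_coordinates <- function(lon, lat, urbanicity, seed = 1L, boundary = NULL,
                                 max_km = c(urban = 2, rural = 5, rural_far = 10),
                                 far_fraction = 0.01) {
  n <- length(lon)
  stopifnot(length(lat) == n, length(urbanicity) %in% c(1L, n))
  urbanicity <- rep_len(urbanicity, n)
  if (!all(urbanicity %in% c("urban", "rural")))
    stop("urbanicity must be 'urban' or 'rural'", call. = FALSE)
  with_seed(seed, {
    cap <- ifelse(urbanicity == "urban", max_km[["urban"]], max_km[["rural"]])
    far <- urbanicity == "rural" & runif(n) < far_fraction
    cap[far] <- max_km[["rural_far"]]
    out_lon <- lon; out_lat <- lat; d_km <- numeric(n)
    todo <- seq_len(n)
    for (attempt in 1:100) {
      if (!length(todo)) break
      ang <- runif(length(todo), 0, 2 * pi)
      d <- runif(length(todo), 0, cap[todo])
      mpd <- meters_per_degree(lat[todo])
      cand_lon <- lon[todo] + (d * 1000 * sin(ang)) / mpd$lon
      cand_lat <- lat[todo] + (d * 1000 * cos(ang)) / mpd$lat
      ok <- if (is.null(boundary)) rep(TRUE, length(todo))
            else points_in_poly(cand_lon, cand_lat, boundary)
      out_lon[todo[ok]] <- cand_lon[ok]
      out_lat[todo[ok]] <- cand_lat[ok]
      d_km[todo[ok]] <- d[ok]
      todo <- todo[!ok]
    }
    if (length(todo)) { # keep originals where no admissible draw was found
      out_lon[todo] <- lon[todo]; out_lat[todo] <- lat[todo]; d_km[todo] <- 0
    }
    tibble::tibble(lon = out_lon, lat = out_lat, displacement_km = d_km)
  })
}
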